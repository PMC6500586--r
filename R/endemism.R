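## Endemism classification across lakes, the high-abundance filter, and
## composition summaries with ground-truth recovery scoring.

lake_map_of <- function(lakes) {
    if (is.data.frame(lakes)) {
        stopifnot(all(c("sample_id", "lake_id") %in% names(lakes)))
        return(stats::setNames(lakes$lake_id, lakes$sample_id))
    }
    if (is.null(names(lakes))) stop("lake map must be named by sample id")
    lakes
}

#' Classify OTUs as ubiquitous, lake-specific or intermediate
#'
#' An OTU is "present" in a lake iff it has a nonzero count in at least one
#' sample of that lake (presence is binary, so the call is invariant to
#' per-sample depth scaling). OTUs present in every lake are ubiquitous,
#' those in exactly one lake are lake-specific, the rest intermediate.
#'
#' @param table an `otu_table` or counts matrix (samples x OTUs).
#' @param lakes sample-to-lake map: named character vector or data frame
#'   with `sample_id`, `lake_id`.
#' @return Data frame of class `endemism_report`: `otu_id`, `lakes_present`,
#'   `class`; the number of lakes is attached as attribute `n_lakes`.
#' @export
classify_endemism <- function(table, lakes) {
    m <- counts_of(table)
    map <- lake_map_of(lakes)
    if (!all(rownames(m) %in% names(map)))
        stop("unmapped sample(s): ",
             paste(setdiff(rownames(m), names(map)), collapse = ", "))
    lake_of <- map[rownames(m)]
    n_lakes <- length(unique(lake_of))
    if (n_lakes < 2)
        stop("endemism is undefined with a single lake")
    pres <- rowsum((m > 0) * 1L, lake_of) > 0
    lakes_present <- colSums(pres)
    cls <- ifelse(lakes_present == n_lakes, "ubiquitous",
                  ifelse(lakes_present == 1, "lake-specific", "intermediate"))
    out <- data.frame(otu_id = colnames(m),
                      lakes_present = as.integer(lakes_present),
                      class = cls, stringsAsFactors = FALSE)
    attr(out, "n_lakes") <- n_lakes
    class(out) <- c("endemism_report", "data.frame")
    out
}

#' High-relative-abundance OTU filter
#'
#' Keeps an OTU iff its within-sample relative abundance strictly exceeds
#' `threshold` in at least one sample (the "> 1% in at least one sample"
#' rule).
#'
#' @param table an `otu_table` or counts matrix.
#' @param threshold relative-abundance cutoff in (0, 1), default 0.01.
#' @return Character vector of retained OTU ids.
#' @export
high_abundance_filter <- function(table, threshold = 0.01) {
    if (threshold <= 0 || threshold >= 1)
        stop("threshold must lie strictly inside (0, 1)")
    m <- counts_of(table)
    totals <- rowSums(m)
    if (any(totals == 0)) stop("sample(s) with zero total counts")
    rel <- m / totals
    colnames(m)[apply(rel > threshold, 2, any)]
}

#' Composition summary at OTU / genus / phylum level
#'
#' Tallies distinct OTUs, genera and phyla for a community subset (whole
#' table, SRP sub-community, or high-abundance SRP), plus the per-phylum
#' percentage of representative OTUs. OTUs without a taxonomy label are
#' tallied as "unclassified", never dropped.
#'
#' @param table an `otu_table` (taxonomy attached via [annotate_otus()], or
#'   supplied separately).
#' @param taxonomy optional taxonomy data frame (`otu_id`, `phylum`,
#'   `genus`) overriding `table$taxonomy`.
#' @param subset `"all"`, `"srp"` or `"high_abundance_srp"`.
#' @param threshold high-abundance cutoff used by the SRP subsets.
#' @return List with `subset`, `n_otus`, `n_genera`, `n_phyla` (named-genus /
#'   named-phylum counts; unclassified reported separately), and
#'   `phylum_pct` (percentages over the subset's OTUs, summing to 100).
#' @export
composition_summary <- function(table, taxonomy = NULL,
                                subset = c("all", "srp",
                                           "high_abundance_srp"),
                                threshold = 0.01) {
    subset <- match.arg(subset)
    stopifnot(inherits(table, "otu_table"))
    taxonomy <- taxonomy %||% table$taxonomy
    otus <- switch(subset,
                   all = colnames(table$counts),
                   srp = srp_otus(table),
                   high_abundance_srp = {
                       srp <- srp_otus(table)
                       intersect(high_abundance_filter(table, threshold), srp)
                   })
    if (!length(otus)) stop("empty OTU subset: ", subset)
    if (is.null(taxonomy)) {
        phy <- rep("unclassified", length(otus))
        gen <- rep("unclassified", length(otus))
    } else {
        i <- match(otus, taxonomy$otu_id)
        phy <- ifelse(is.na(i), "unclassified", taxonomy$phylum[i])
        gen <- ifelse(is.na(i), "unclassified", taxonomy$genus[i])
        phy[is.na(phy)] <- "unclassified"
        gen[is.na(gen)] <- "unclassified"
    }
    pct <- 100 * table(phy) / length(otus)
    list(subset = subset,
         n_otus = length(otus),
         n_genera = length(setdiff(unique(gen), "unclassified")),
         n_phyla = length(setdiff(unique(phy), "unclassified")),
         n_unclassified_otus = sum(gen == "unclassified"),
         phylum_pct = sort(as.vector(pct), decreasing = TRUE) |>
             stats::setNames(names(pct)[order(pct, decreasing = TRUE)]))
}

#' Endemism class fractions
#'
#' Percentage of OTUs per endemism class, reported at 0.1% resolution and at
#' whole-percent rounding. Accepts an `endemism_report` or named class
#' counts.
#'
#' @param report an `endemism_report` from [classify_endemism()], or a named
#'   integer vector of class counts.
#' @param total total OTU count (required when `report` is a count vector
#'   whose sum is not the total).
#' @return Data frame with `class`, `count`, `total`, `pct` (one decimal)
#'   and `pct_whole`.
#' @export
endemism_fractions <- function(report, total = NULL) {
    if (inherits(report, "endemism_report") || is.data.frame(report)) {
        counts <- table(report$class)
        total <- total %||% nrow(report)
    } else {
        counts <- report
        total <- total %||% sum(report)
    }
    if (is.null(total) || total == 0) stop("zero total OTU count")
    data.frame(class = names(counts),
               count = as.integer(counts),
               total = as.integer(total),
               pct = round(100 * as.integer(counts) / total, 1),
               pct_whole = round(100 * as.integer(counts) / total),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Score recovery of planted endemism classes
#'
#' Matches recovered OTUs to planted taxa (via [annotate_otus()] labels) and
#' scores the fraction of planted taxa whose recovered endemism class equals
#' the planted one. Recovered OTUs that map to no planted taxon (spurious
#' error clusters) are counted separately.
#'
#' @param table an annotated `otu_table`.
#' @param truth the `epic_truth` used for the simulation.
#' @param lakes sample-to-lake map (defaults to `truth$samples`).
#' @return List with `fraction_correct`, `n_matched`, `n_spurious`, and the
#'   merged per-OTU data frame `detail`.
#' @export
endemism_recovery <- function(table, truth, lakes = NULL) {
    stopifnot(inherits(table, "otu_table"))
    if (is.null(table$taxonomy)) table <- annotate_otus(table, truth)
    lakes <- lakes %||% truth$samples
    rep_cls <- classify_endemism(table, lakes)
    tax <- table$taxonomy
    detail <- merge(rep_cls, tax[, c("otu_id", "planted_taxon",
                                     "endemism_class")], by = "otu_id")
    matched <- !is.na(detail$planted_taxon)
    ## planted class per matched OTU, one row per planted taxon (a planted
    ## taxon recovered as several OTUs counts once, via its dominant OTU)
    det_m <- detail[matched, ]
    correct <- det_m$class == det_m$endemism_class
    list(fraction_correct = if (nrow(det_m)) mean(correct) else NA_real_,
         n_matched = nrow(det_m),
         n_spurious = sum(!matched),
         detail = detail)
}

#' Write the per-OTU endemism table as TSV
#'
#' @param report an `endemism_report`.
#' @param path TSV path.
#' @export
write_endemism_report <- function(report, path) {
    utils::write.table(report, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
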