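## Joint OTU construction: pooling, dereplication, chimera screen, greedy
## 97% clustering (singletons kept), table building and rarefaction.

#' Clustering parameters
#'
#' @param identity_threshold minimum pairwise identity to join a centroid
#'   (default 0.97; the exact-97% boundary is admitted).
#' @param chimera_screen run the two-parent chimera screen before clustering.
#' @param abundance_skew minimum parent/child abundance ratio for the screen
#'   (default 2).
#' @param chimera_identity segment identity required of chimera parents
#'   (default 0.99).
#' @param min_segment minimum flank length on each side of a chimera
#'   breakpoint (default 30).
#' @return An object of class `cluster_params`.
#' @export
cluster_params <- function(identity_threshold = 0.97, chimera_screen = TRUE,
                           abundance_skew = 2, chimera_identity = 0.99,
                           min_segment = 30) {
    if (identity_threshold <= 0 || identity_threshold > 1)
        stop("identity_threshold must lie in (0, 1]")
    structure(list(identity_threshold = identity_threshold,
                   chimera_screen = chimera_screen,
                   abundance_skew = abundance_skew,
                   chimera_identity = chimera_identity,
                   min_segment = as.integer(min_segment)),
              class = "cluster_params")
}

#' Pool per-sample 16S streams from both libraries
#'
#' Combines the epicPCR-derived 16S fragments with the bulk 16S amplicons
#' into one labelled pool, preserving each read's sample id and provenance.
#'
#' @param epic named list (sample id -> read set or character vector) of
#'   epicPCR 16S fragments.
#' @param bulk named list of bulk 16S amplicons.
#' @param samples optional sample roster; ids outside it are an error.
#' @return Data frame with columns `sample_id`, `source` (`epic`/`bulk`) and
#'   `seq`.
#' @export
combine_streams <- function(epic, bulk, samples = NULL) {
    grab <- function(lst, src) {
        if (is.null(lst) || !length(lst)) return(NULL)
        do.call(rbind, lapply(names(lst), function(s) {
            x <- lst[[s]]
            seqs <- if (is.data.frame(x)) x$seq else as.character(x)
            if (!length(seqs)) return(NULL)
            data.frame(sample_id = s, source = src, seq = seqs,
                       stringsAsFactors = FALSE)
        }))
    }
    pool <- rbind(grab(epic, "epic"), grab(bulk, "bulk"))
    if (is.null(pool))
        pool <- data.frame(sample_id = character(), source = character(),
                           seq = character(), stringsAsFactors = FALSE)
    roster <- samples %||% unique(pool$sample_id)
    if (!all(pool$sample_id %in% roster))
        stop("unknown sample id(s): ",
             paste(setdiff(pool$sample_id, roster), collapse = ", "))
    rownames(pool) <- NULL
    pool
}

#' Dereplicate a sequence pool
#'
#' @param pool data frame from [combine_streams()] (only `seq` is used).
#' @return List with `uniques` (data frame `seq`, `abundance`, sorted by
#'   decreasing abundance, ties broken lexicographically by sequence) and
#'   `map` (index of each pool read into `uniques`).
#' @export
dereplicate <- function(pool) {
    seqs <- if (is.data.frame(pool)) pool$seq else as.character(pool)
    tab <- table(seqs)
    uniq <- data.frame(seq = names(tab), abundance = as.integer(tab),
                       stringsAsFactors = FALSE)
    uniq <- uniq[order(-uniq$abundance, uniq$seq), , drop = FALSE]
    rownames(uniq) <- NULL
    list(uniques = uniq, map = match(seqs, uniq$seq))
}

#' Flag two-parent chimeras among dereplicated uniques
#'
#' A sequence is flagged iff some breakpoint splits it into a left segment at
#' least 99% identical to the prefix of one kept sequence at twice its
#' abundance or more, and a right segment at least 99% identical to the
#' suffix of a different such sequence. Both flanks must reach `min_segment`
#' bases, and a candidate that any single eligible parent already explains
#' end-to-end at the segment identity is treated as a sequence variant, not
#' a chimera (otherwise every point-error read of an abundant taxon would be
#' removed). Flagged sequences are excluded from the potential-parent set as
#' the scan proceeds in abundance order.
#'
#' @param uniques data frame from [dereplicate()] (`seq`, `abundance`),
#'   sorted by decreasing abundance.
#' @param params a [cluster_params()].
#' @return List with `kept` and `flagged` subsets of `uniques`.
#' @export
chimera_screen <- function(uniques, params = cluster_params()) {
    if (!nrow(uniques))
        return(list(kept = uniques, flagged = uniques))
    flags <- cpp_chimera_flags(uniques$seq, as.numeric(uniques$abundance),
                               params$abundance_skew, params$chimera_identity,
                               params$min_segment)
    list(kept = uniques[!flags, , drop = FALSE],
         flagged = uniques[flags, , drop = FALSE])
}

#' Pairwise sequence identity under the clustering convention
#'
#' Full global (Needleman-Wunsch) alignment with match +1, mismatch -1,
#' linear gap -2 and end gaps penalized; identity is matches / alignment
#' columns of the optimal-score alignment, so every gap column counts
#' against. Vectors are compared elementwise (one argument may be length 1).
#'
#' @param a,b character vectors of DNA sequences.
#' @return Numeric vector of identities in \[0, 1\].
#' @export
sequence_identity <- function(a, b) {
    cpp_seq_identity(as.character(a), as.character(b))
}

#' Greedy abundance-sorted centroid clustering
#'
#' Scans uniques in decreasing-abundance order; each sequence joins the first
#' existing centroid whose identity (global alignment, gaps counting
#' against, matches / alignment columns) reaches the threshold, else founds a
#' new centroid. Singletons are never discarded. The representative of each
#' OTU is its most abundant member (the founder; ties were broken
#' lexicographically upstream).
#'
#' @param uniques data frame (`seq`, `abundance`) sorted by decreasing
#'   abundance.
#' @param params a [cluster_params()].
#' @return List with `otu` (integer OTU index per unique), `otu_ids`
#'   (`OTU0001`, ...), and `representatives` (named character vector).
#' @export
greedy_cluster <- function(uniques, params = cluster_params()) {
    n <- nrow(uniques)
    otu <- integer(n)
    centroids <- integer(0)
    thr <- params$identity_threshold
    for (i in seq_len(n)) {
        hit <- if (length(centroids))
            cpp_first_match(uniques$seq[i], uniques$seq[centroids], thr)
        else 0L
        if (hit == 0L) {
            centroids <- c(centroids, i)
            otu[i] <- length(centroids)
        } else {
            otu[i] <- hit
        }
    }
    otu_ids <- sprintf("OTU%04d", seq_along(centroids))
    list(otu = otu, otu_ids = otu_ids,
         representatives = stats::setNames(uniques$seq[centroids], otu_ids))
}

#' Cluster a pooled read set into an OTU table
#'
#' Full joint-OTU construction: dereplication, optional chimera screen,
#' greedy clustering at the identity threshold, then per-sample counting
#' split by read provenance (epicPCR vs bulk).
#'
#' @param pool data frame from [combine_streams()].
#' @param params a [cluster_params()].
#' @return An `otu_table` object: list with `counts` (samples x OTUs),
#'   `counts_epic`, `counts_bulk`, `representatives`, `n_chimera` (reads
#'   removed per sample), and optional `taxonomy` (see [annotate_otus()]).
#' @export
cluster_pool <- function(pool, params = cluster_params()) {
    dr <- dereplicate(pool)
    uniq <- dr$uniques
    flagged_seqs <- character(0)
    if (params$chimera_screen) {
        cs <- chimera_screen(uniq, params)
        flagged_seqs <- cs$flagged$seq
        uniq <- cs$kept
    }
    cl <- greedy_cluster(uniq, params)
    samples <- unique(pool$sample_id)
    otu_of_read <- cl$otu[match(pool$seq, uniq$seq)]  # NA for chimeric reads
    keep <- !is.na(otu_of_read)
    count_mat <- function(sel) {
        m <- matrix(0L, length(samples), length(cl$otu_ids),
                    dimnames = list(samples, cl$otu_ids))
        if (any(sel)) {
            t0 <- table(factor(pool$sample_id[sel], levels = samples),
                        factor(otu_of_read[sel],
                               levels = seq_along(cl$otu_ids)))
            m[] <- as.integer(t0)
        }
        m
    }
    counts_epic <- count_mat(keep & pool$source == "epic")
    counts_bulk <- count_mat(keep & pool$source == "bulk")
    n_chim <- table(factor(pool$sample_id[!keep], levels = samples))
    structure(list(counts = counts_epic + counts_bulk,
                   counts_epic = counts_epic, counts_bulk = counts_bulk,
                   representatives = cl$representatives,
                   n_chimera = stats::setNames(as.integer(n_chim), samples),
                   taxonomy = NULL),
              class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
    cat("OTU table:", nrow(x$counts), "samples x", ncol(x$counts), "OTUs;",
        sum(x$counts), "reads (", sum(x$counts_epic), "epicPCR,",
        sum(x$counts_bulk), "bulk );", sum(x$n_chimera),
        "chimeric reads removed\n")
    invisible(x)
}

#' OTUs observed in the epicPCR stream (the SRP sub-community)
#'
#' @param table an `otu_table`.
#' @return Character vector of OTU ids with at least one epicPCR-derived
#'   read.
#' @export
srp_otus <- function(table) {
    colnames(table$counts_epic)[colSums(table$counts_epic) > 0]
}

#' Subset an OTU table by OTUs and/or samples
#'
#' @param table an `otu_table`.
#' @param otus OTU ids to keep (default all).
#' @param samples sample ids to keep (default all).
#' @return An `otu_table`.
#' @export
subset_otu_table <- function(table, otus = NULL, samples = NULL) {
    otus <- otus %||% colnames(table$counts)
    samples <- samples %||% rownames(table$counts)
    out <- table
    for (f in c("counts", "counts_epic", "counts_bulk"))
        out[[f]] <- table[[f]][samples, otus, drop = FALSE]
    out$representatives <- table$representatives[otus]
    out$n_chimera <- table$n_chimera[samples]
    if (!is.null(table$taxonomy))
        out$taxonomy <- table$taxonomy[match(otus, table$taxonomy$otu_id), ,
                                       drop = FALSE]
    out
}

#' Rarefy an OTU table to a fixed depth
#'
#' Per sample, `depth` reads are drawn without replacement; samples with
#' fewer reads than `depth` are dropped with a warning. Provenance-split
#' counts are rarefied jointly (each read keeps its source label).
#'
#' @param table an `otu_table`.
#' @param depth target depth (default 10000).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return A rarefied `otu_table` whose rows each sum to exactly `depth`.
#' @export
rarefy_table <- function(table, depth = 10000, seed = 1L) {
    stopifnot(inherits(table, "otu_table"))
    if (depth <= 0) stop("depth must be positive")
    totals <- rowSums(table$counts)
    keep <- totals >= depth
    if (!any(keep))
        stop("all samples fall below the rarefaction depth (", depth, ")")
    if (any(!keep))
        warning(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
                paste(names(totals)[!keep], collapse = ", "))
    set.seed(as.integer(seed))
    out <- subset_otu_table(table, samples = rownames(table$counts)[keep])
    n_otu <- ncol(out$counts)
    for (s in rownames(out$counts)) {
        ## joint draw over (otu, source) cells so provenance splits stay
        ## consistent with the rarefied totals
        cells <- c(out$counts_epic[s, ], out$counts_bulk[s, ])
        drawn <- draw_without_replacement(cells, depth)
        out$counts_epic[s, ] <- drawn[seq_len(n_otu)]
        out$counts_bulk[s, ] <- drawn[n_otu + seq_len(n_otu)]
    }
    out$counts <- out$counts_epic + out$counts_bulk
    out
}

## Multivariate hypergeometric draw: depth items without replacement from
## cells with the given counts.
draw_without_replacement <- function(cells, depth) {
    ids <- rep(seq_along(cells), cells)
    take <- sample(ids, depth, replace = FALSE)
    as.integer(tabulate(take, nbins = length(cells)))
}

#' Annotate recovered OTUs with planted truth
#'
#' Maps each representative sequence to its closest planted template (exact
#' match, then Hamming for equal lengths, then alignment) and attaches the
#' planted taxonomy, endemism class and SRP flag. Representatives below
#' `min_identity` to every template are labelled unclassified.
#'
#' @param table an `otu_table`.
#' @param truth an `epic_truth`.
#' @param min_identity minimum identity to accept a template match
#'   (default 0.97).
#' @return The table with a `taxonomy` data frame (`otu_id`, `planted_taxon`,
#'   `phylum`, `genus`, `srp`, `endemism_class`).
#' @export
annotate_otus <- function(table, truth, min_identity = 0.97) {
    reps <- table$representatives
    otus <- truth$otus
    hit <- match(reps, otus$seq16s)
    for (i in which(is.na(hit))) {
        id <- sequence_identity(reps[[i]], otus$seq16s)
        best <- which.max(id)
        if (id[best] >= min_identity) hit[i] <- best
    }
    tax <- data.frame(
        otu_id = names(reps),
        planted_taxon = ifelse(is.na(hit), NA_character_, otus$otu_id[hit]),
        phylum = ifelse(is.na(hit), "unclassified", otus$phylum[hit]),
        genus = ifelse(is.na(hit), "unclassified", otus$genus[hit]),
        srp = ifelse(is.na(hit), NA, otus$srp[hit]),
        endemism_class = ifelse(is.na(hit), NA_character_,
                                otus$endemism_class[hit]),
        stringsAsFactors = FALSE)
    table$taxonomy <- tax
    table
}

#' Write / read an OTU table as TSV (plus representative FASTA)
#'
#' Rows are OTU ids, columns are samples; a companion FASTA holds the
#' representative sequences.
#'
#' @param table an `otu_table`.
#' @param path TSV path; the FASTA is written next to it as
#'   `<path>.reps.fasta`.
#' @export
write_otu_table <- function(table, path) {
    m <- t(table$counts)
    out <- data.frame(otu_id = rownames(m), m, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_fasta(table$representatives, paste0(path, ".reps.fasta"))
    invisible(path)
}

#' @rdname write_otu_table
#' @export
read_otu_table <- function(path) {
    x <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    m <- t(as.matrix(x[, -1, drop = FALSE]))
    colnames(m) <- x$otu_id
    mode(m) <- "integer"
    reps_path <- paste0(path, ".reps.fasta")
    reps <- if (file.exists(reps_path)) read_fasta(reps_path) else NULL
    structure(list(counts = m, counts_epic = NULL, counts_bulk = NULL,
                   representatives = reps, n_chimera = NULL, taxonomy = NULL),
              class = "otu_table")
}
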