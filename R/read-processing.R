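## Demultiplexing, primer trimming, pair merging, fused-read splitting and
## windowed quality filtering, with per-stage accounting.

#' Demultiplexing rule
#'
#' @param barcodes named character vector (names are sample ids) or a barcode
#'   table data frame with `sample_id` and `barcode` columns.
#' @param max_mismatch maximum barcode mismatches (default 1).
#' @return An object of class `demux_rule`.
#' @export
demux_rule <- function(barcodes, max_mismatch = 1) {
    if (is.data.frame(barcodes))
        barcodes <- stats::setNames(barcodes$barcode, barcodes$sample_id)
    if (is.null(names(barcodes)) || any(names(barcodes) == ""))
        stop("barcodes must be named by sample id")
    if (anyDuplicated(names(barcodes)))
        stop("duplicate sample ids in barcode table")
    if (length(unique(nchar(barcodes))) != 1)
        stop("all barcodes must have the same length")
    if (length(barcodes) > 1) {
        pairs <- utils::combn(length(barcodes), 2)
        d <- cpp_hamming(barcodes[pairs[1, ]], barcodes[pairs[2, ]])
        if (any(d <= 2 * max_mismatch))
            stop("ambiguous barcode table: pairwise Hamming distance must ",
                 "exceed 2 * max_mismatch")
    }
    structure(list(barcodes = barcodes, max_mismatch = max_mismatch),
              class = "demux_rule")
}

#' Assign reads to samples by barcode
#'
#' A read is assigned iff exactly one barcode lies within `max_mismatch` of
#' its prefix; the barcode is stripped from assigned forward reads. An
#' optional mate vector is partitioned identically (untouched otherwise).
#'
#' @param reads a [read_set()] whose sequences start with the barcode.
#' @param rule a [demux_rule()].
#' @param mate optional [read_set()] of reverse mates, same order.
#' @return List with `samples` (named list; per sample either a read set or,
#'   with a mate, `list(r1, r2)`) and `unassigned`.
#' @export
demultiplex <- function(reads, rule, mate = NULL) {
    stopifnot(inherits(rule, "demux_rule"))
    reads <- as_read_set(reads)
    if (!is.null(mate)) {
        mate <- as_read_set(mate)
        stopifnot(nrow(mate) == nrow(reads))
    }
    bl <- nchar(rule$barcodes[[1]])
    idx <- cpp_assign_barcode(reads$seq, unname(rule$barcodes),
                              rule$max_mismatch)
    samples <- vector("list", length(rule$barcodes))
    names(samples) <- names(rule$barcodes)
    for (j in seq_along(rule$barcodes)) {
        sel <- which(idx == j)
        r1 <- subset_reads(reads, sel)
        r1$seq <- substring(r1$seq, bl + 1)
        r1$qual <- substring(r1$qual, bl + 1)
        samples[[j]] <- if (is.null(mate)) r1
                        else list(r1 = r1, r2 = subset_reads(mate, sel))
    }
    un <- which(idx <= 0)
    unassigned <- if (is.null(mate)) subset_reads(reads, un)
                  else list(r1 = subset_reads(reads, un),
                            r2 = subset_reads(mate, un))
    list(samples = samples, unassigned = unassigned)
}

#' Trim a 5' primer with IUPAC degeneracy
#'
#' The primer must match at the read start within `max_mismatch` under IUPAC
#' semantics (e.g. M matches A or C, H matches A/C/T, V matches A/C/G,
#' W matches A/T); the matched span is removed. Reads without an acceptable
#' match are rejected.
#'
#' @param reads a [read_set()].
#' @param primer IUPAC primer sequence.
#' @param max_mismatch allowed mismatches (default 1).
#' @return List with `kept` (trimmed) and `rejected` read sets.
#' @export
trim_primer <- function(reads, primer, max_mismatch = 1) {
    if (!nzchar(primer)) stop("primer must be non-empty")
    reads <- as_read_set(reads)
    pl <- nchar(primer)
    mm <- cpp_iupac_mismatch(reads$seq, primer, 0L)
    ok <- !is.na(mm) & mm <= max_mismatch
    kept <- subset_reads(reads, ok)
    kept$seq <- substring(kept$seq, pl + 1)
    kept$qual <- substring(kept$qual, pl + 1)
    list(kept = kept, rejected = subset_reads(reads, !ok))
}

#' Merge read pairs by best ungapped overlap
#'
#' The reverse mate is reverse-complemented internally; candidate overlaps of
#' at least `min_overlap` bases are scored by mismatch fraction and the best
#' (ties to the longer overlap) is taken, provided its mismatch fraction does
#' not exceed `max_mismatch_frac`. Disagreeing overlap bases are resolved
#' toward the higher quality score; merged quality is the positional maximum.
#'
#' @param fwd,rev forward and reverse [read_set()]s in sequencer orientation.
#' @param min_overlap minimum acceptable overlap (default 30).
#' @param max_mismatch_frac maximum mismatch fraction in the overlap.
#' @return List with `merged` and `rejected` (forward reads of unmerged
#'   pairs).
#' @export
merge_pairs <- function(fwd, rev, min_overlap = 30, max_mismatch_frac = 0.25) {
    fwd <- as_read_set(fwd); rev <- as_read_set(rev)
    stopifnot(nrow(fwd) == nrow(rev))
    if (!nrow(fwd)) return(list(merged = empty_read_set(),
                                rejected = empty_read_set()))
    rc <- revcomp(rev$seq)
    rq <- rev_string(rev$qual)
    res <- cpp_merge_pairs(fwd$seq, fwd$qual, rc, rq,
                           as.integer(min_overlap), max_mismatch_frac)
    ok <- res$status == 0
    merged <- read_set(fwd$id[ok], res$seq[ok], res$qual[ok])
    list(merged = merged, rejected = subset_reads(fwd, !ok))
}

#' Fused-read splitting rule
#'
#' @param functional_prefix_len length of the leading dsrB fragment
#'   (default 30).
#' @param bridge IUPAC sequence of the bridging primer.
#' @param bridge_max_mismatch mismatches tolerated when anchoring the bridge
#'   (default 2).
#' @return An object of class `split_rule`.
#' @export
split_rule <- function(functional_prefix_len = 30,
                       bridge = "GWATTACCGCGGCKGCTG",
                       bridge_max_mismatch = 2) {
    if (functional_prefix_len <= 0)
        stop("functional_prefix_len must be positive")
    if (!nzchar(bridge)) stop("bridge must be non-empty")
    structure(list(functional_prefix_len = as.integer(functional_prefix_len),
                   bridge = bridge,
                   bridge_max_mismatch = bridge_max_mismatch),
              class = "split_rule")
}

#' Split merged fused reads into dsrB and 16S fragments
#'
#' The first `functional_prefix_len` bases are emitted as the dsrB fragment;
#' the bridging primer is located at its expected position immediately after
#' (anchored search, IUPAC-aware, within `bridge_max_mismatch`) and removed;
#' the remainder is the 16S fragment. Reads whose bridge cannot be located are
#' rejected separately, distinguishing malformed fusions.
#'
#' @param reads merged fused [read_set()].
#' @param rule a [split_rule()].
#' @return List with `dsrb`, `ssu` (fragments carry the parent read id) and
#'   `rejected`.
#' @export
split_fused <- function(reads, rule) {
    stopifnot(inherits(rule, "split_rule"))
    reads <- as_read_set(reads)
    fl <- rule$functional_prefix_len
    bl <- nchar(rule$bridge)
    mm <- cpp_iupac_mismatch(reads$seq, rule$bridge, fl)
    ok <- !is.na(mm) & mm <= rule$bridge_max_mismatch &
        nchar(reads$seq) > fl + bl
    kept <- subset_reads(reads, ok)
    dsrb <- read_set(kept$id, substr(kept$seq, 1, fl), substr(kept$qual, 1, fl))
    ssu <- read_set(kept$id, substring(kept$seq, fl + bl + 1),
                    substring(kept$qual, fl + bl + 1))
    list(dsrb = dsrb, ssu = ssu, rejected = subset_reads(reads, !ok))
}

#' Quality / length filtering rule
#'
#' @param q_threshold Phred threshold; a window whose mean quality is at or
#'   below it truncates the read (default 20).
#' @param window sliding-window size (default 5).
#' @param min_len,max_len accepted length range after truncation
#'   (defaults 245 / 260).
#' @param reject_ambiguous discard reads containing N (default TRUE).
#' @return An object of class `filter_rule`.
#' @export
filter_rule <- function(q_threshold = 20, window = 5,
                        min_len = 245, max_len = 260,
                        reject_ambiguous = TRUE) {
    if (min_len > max_len) stop("min_len must not exceed max_len")
    if (window < 1) stop("window must be >= 1")
    structure(list(q_threshold = q_threshold, window = as.integer(window),
                   min_len = as.integer(min_len),
                   max_len = as.integer(max_len),
                   reject_ambiguous = reject_ambiguous),
              class = "filter_rule")
}

#' Windowed quality filter with length and ambiguity rules
#'
#' A window of size `window` slides 5' to 3'; the read is truncated at the
#' first window whose mean quality is at or below `q_threshold`. The
#' truncated read is kept iff it contains no N (when `reject_ambiguous`) and
#' its length lies within `[min_len, max_len]`. The operation is idempotent.
#'
#' @param reads a [read_set()].
#' @param rule a [filter_rule()].
#' @return List with `kept` (possibly truncated) and `rejected`, the latter
#'   carrying a `reason` column (`quality_length`, `too_short`, `too_long`,
#'   `ambiguous`).
#' @export
quality_filter <- function(reads, rule = filter_rule()) {
    stopifnot(inherits(rule, "filter_rule"))
    reads <- as_read_set(reads)
    if (!nrow(reads)) {
        rej <- reads; rej$reason <- character(0)
        return(list(kept = reads, rejected = rej))
    }
    keep_len <- cpp_window_keep_len(reads$qual, rule$q_threshold, rule$window)
    trunc <- reads
    trunc$seq <- substr(reads$seq, 1, keep_len)
    trunc$qual <- substr(reads$qual, 1, keep_len)
    len <- nchar(trunc$seq)
    has_n <- grepl("N", trunc$seq, fixed = TRUE)
    reason <- rep(NA_character_, nrow(reads))
    reason[len < rule$min_len] <- "too_short"
    reason[len > rule$max_len] <- "too_long"
    if (rule$reject_ambiguous) reason[is.na(reason) & has_n] <- "ambiguous"
    ok <- is.na(reason)
    kept <- subset_reads(trunc, ok)
    rejected <- subset_reads(trunc, !ok)
    rejected$reason <- reason[!ok]
    list(kept = kept, rejected = rejected)
}

## ---- stage accounting -----------------------------------------------------

new_stage_report <- function() {
    out <- data.frame(sample_id = character(), stage = character(),
                      n_in = integer(), n_out = integer(),
                      stringsAsFactors = FALSE)
    class(out) <- c("stage_report", "data.frame")
    out
}

add_stage <- function(report, sample_id, stage, n_in, n_out) {
    row <- data.frame(sample_id = sample_id, stage = stage,
                      n_in = as.integer(n_in), n_out = as.integer(n_out),
                      stringsAsFactors = FALSE)
    out <- rbind(report, row)
    class(out) <- c("stage_report", "data.frame")
    out
}

#' Validate per-stage read conservation
#'
#' Checks that within every sample the counts are non-increasing along the
#' pipeline and that each stage's input equals its output plus its discards.
#'
#' @param report a `stage_report` produced by [process_fused_reads()] or
#'   [process_bulk_reads()].
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_stage_report <- function(report) {
    for (s in unique(report$sample_id)) {
        r <- report[report$sample_id == s, ]
        if (any(r$n_out > r$n_in))
            stop("stage output exceeds input for sample ", s)
        if (nrow(r) > 1 && any(r$n_in[-1] != r$n_out[-nrow(r)]))
            stop("stage chain broken for sample ", s)
    }
    invisible(TRUE)
}

#' Write a stage report as TSV
#'
#' @param report a `stage_report`.
#' @param path TSV path.
#' @export
write_stage_report <- function(report, path) {
    utils::write.table(report, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

## ---- per-library pipelines ------------------------------------------------

#' Process a fused (epicPCR) library end to end
#'
#' Demultiplex by barcode, trim both primers, merge pairs, split off the dsrB
#' fragment and the bridging primer, then quality/length-filter the 16S
#' fragments. Per-sample, per-stage counts are accounted in a stage report.
#'
#' @param r1,r2 forward/reverse [read_set()]s or FASTQ paths.
#' @param barcodes barcode table (data frame with `sample_id`, `barcode`,
#'   `fwd_primer`, `rev_primer`) or named barcode vector plus explicit
#'   primers.
#' @param fwd_primer,rev_primer primers, taken from the barcode table when
#'   omitted.
#' @param split a [split_rule()].
#' @param filter a [filter_rule()].
#' @param min_overlap,max_mismatch_frac merge parameters.
#' @param max_mismatch barcode/primer mismatch tolerance.
#' @return List with `ssu` (named list of per-sample 16S read sets), `dsrb`
#'   (per-sample dsrB fragments) and `report` (a `stage_report`).
#' @export
process_fused_reads <- function(r1, r2, barcodes,
                                fwd_primer = NULL, rev_primer = NULL,
                                split = split_rule(),
                                filter = filter_rule(),
                                min_overlap = 30, max_mismatch_frac = 0.25,
                                max_mismatch = 1) {
    process_library(r1, r2, barcodes, fwd_primer, rev_primer, split, filter,
                    min_overlap, max_mismatch_frac, max_mismatch)
}

#' Process a bulk 16S library end to end
#'
#' As [process_fused_reads()] but without the splitting stage: demultiplex,
#' trim primers, merge, quality/length-filter.
#'
#' @inheritParams process_fused_reads
#' @return List with `ssu` (per-sample read sets) and `report`.
#' @export
process_bulk_reads <- function(r1, r2, barcodes,
                               fwd_primer = NULL, rev_primer = NULL,
                               filter = filter_rule(),
                               min_overlap = 30, max_mismatch_frac = 0.25,
                               max_mismatch = 1) {
    process_library(r1, r2, barcodes, fwd_primer, rev_primer, NULL, filter,
                    min_overlap, max_mismatch_frac, max_mismatch)
}

process_library <- function(r1, r2, barcodes, fwd_primer, rev_primer,
                            split, filter, min_overlap, max_mismatch_frac,
                            max_mismatch) {
    if (is.character(r1) && length(r1) == 1) r1 <- read_fastq(r1)
    if (is.character(r2) && length(r2) == 1) r2 <- read_fastq(r2)
    if (is.data.frame(barcodes)) {
        fwd_primer <- fwd_primer %||% barcodes$fwd_primer[1]
        rev_primer <- rev_primer %||% barcodes$rev_primer[1]
    }
    if (is.null(fwd_primer) || is.null(rev_primer))
        stop("primers must be given explicitly or via the barcode table")
    rule <- demux_rule(barcodes, max_mismatch)
    dm <- demultiplex(r1, rule, mate = r2)
    report <- new_stage_report()
    ssu_out <- list(); dsrb_out <- list()
    n_total <- nrow(as_read_set(r1))
    report <- add_stage(report, "(all)", "input", n_total, n_total)
    report <- add_stage(report, "(all)", "demux", n_total,
                        n_total - nrow(dm$unassigned$r1))
    for (s in names(dm$samples)) {
        pair <- dm$samples[[s]]
        n0 <- nrow(pair$r1)
        report <- add_stage(report, s, "demux_assigned", n0, n0)
        t1 <- trim_primer(pair$r1, fwd_primer, max_mismatch)
        keep_ids <- t1$kept$id
        r2k <- subset_reads(pair$r2, pair$r1$id %in% keep_ids)
        t2 <- trim_primer(r2k, rev_primer, max_mismatch)
        keep2 <- sub("/2$", "", t2$kept$id)
        r1k <- subset_reads(t1$kept, t1$kept$id %in% keep2)
        report <- add_stage(report, s, "primer", n0, nrow(r1k))
        mg <- merge_pairs(r1k, t2$kept, min_overlap, max_mismatch_frac)
        report <- add_stage(report, s, "merge", nrow(r1k), nrow(mg$merged))
        cur <- mg$merged
        if (!is.null(split)) {
            sp <- split_fused(cur, split)
            report <- add_stage(report, s, "split", nrow(cur), nrow(sp$ssu))
            dsrb_out[[s]] <- sp$dsrb
            cur <- sp$ssu
        }
        qf <- quality_filter(cur, filter)
        report <- add_stage(report, s, "quality", nrow(cur), nrow(qf$kept))
        ssu_out[[s]] <- qf$kept
    }
    validate_stage_report(report[!report$sample_id %in% "(all)", ])
    out <- list(ssu = ssu_out, report = report)
    if (!is.null(split)) out$dsrb <- dsrb_out
    out
}
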