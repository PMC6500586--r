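## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a read set
#'
#' A read set is the package's in-memory form of a FASTQ batch: a data frame
#' with columns `id`, `seq` (DNA over A/C/G/T/N) and `qual` (Phred+33 string,
#' same length as `seq`).
#'
#' @param id character vector of read identifiers.
#' @param seq character vector of sequences.
#' @param qual character vector of Phred+33 quality strings.
#' @return A `data.frame` of class `read_set`.
#' @export
read_set <- function(id, seq, qual) {
    stopifnot(length(id) == length(seq), length(seq) == length(qual))
    if (length(seq) && any(nchar(seq) != nchar(qual)))
        stop("sequence and quality strings must have equal lengths")
    out <- data.frame(id = as.character(id), seq = as.character(seq),
                      qual = as.character(qual), stringsAsFactors = FALSE)
    class(out) <- c("read_set", "data.frame")
    out
}

empty_read_set <- function() read_set(character(), character(), character())

as_read_set <- function(x) {
    if (inherits(x, "read_set")) return(x)
    if (is.data.frame(x) && all(c("id", "seq", "qual") %in% names(x)))
        return(read_set(x$id, x$seq, x$qual))
    stop("cannot coerce object to read_set")
}

subset_reads <- function(reads, keep) {
    out <- reads[keep, , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("read_set", "data.frame")
    out
}

## Reverse complement / string reversal via Biostrings.
revcomp <- function(x) {
    if (!length(x)) return(character())
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

rev_string <- function(x) {
    if (!length(x)) return(character())
    as.character(Biostrings::reverse(Biostrings::BStringSet(x)))
}

phred_string <- function(q, len) {
    ## constant-quality helper: one Phred value -> string of length len
    vapply(len, function(L) strrep(intToUtf8(q + 33L), L), character(1))
}

qual_to_int <- function(qual) utf8ToInt(qual) - 33L

random_dna <- function(n, len, gc = 0.5) {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    vapply(seq_len(n), function(i) {
        paste(sample(names(p), if (length(len) > 1) len[i] else len,
                     replace = TRUE, prob = p), collapse = "")
    }, character(1))
}

## Resolve IUPAC degeneracies to a concrete instance, one random choice per
## degenerate position per string.
IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

resolve_iupac <- function(pattern, n) {
    if (n == 0) return(character())
    chars <- strsplit(pattern, "")[[1]]
    degenerate <- !chars %in% c("A", "C", "G", "T")
    if (!any(degenerate)) return(rep(pattern, n))
    m <- matrix(chars, nrow = n, ncol = length(chars), byrow = TRUE)
    for (j in which(degenerate))
        m[, j] <- sample(IUPAC_SETS[[chars[j]]], n, replace = TRUE)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

## Largest-remainder apportionment of `depth` reads over probabilities p.
## Every taxon with p > 0 is guaranteed at least one read (when depth
## permits): planted presence must be recoverable deterministically.
alloc_counts <- function(p, depth) {
    stopifnot(depth >= 0, all(p >= 0))
    if (sum(p) == 0) stop("cannot allocate reads: all abundances are zero")
    p <- p / sum(p)
    raw <- depth * p
    base <- floor(raw)
    r <- depth - sum(base)
    if (r > 0) {
        idx <- order(raw - base, decreasing = TRUE)[seq_len(r)]
        base[idx] <- base[idx] + 1
    }
    zero <- which(p > 0 & base == 0)
    for (i in zero) {
        big <- which.max(base)
        if (base[big] < 2) break
        base[big] <- base[big] - 1
        base[i] <- 1
    }
    as.integer(base)
}

## Validate a square labeled distance matrix.
check_distance_matrix <- function(d, name = "distance matrix") {
    if (!is.matrix(d) || nrow(d) != ncol(d))
        stop(name, " must be a square matrix")
    if (!isTRUE(all.equal(d, t(d), tolerance = 1e-10, check.attributes = FALSE)))
        stop(name, " must be symmetric")
    if (any(abs(diag(d)) > 1e-12)) stop(name, " must have a zero diagonal")
    if (any(d < -1e-12)) stop(name, " must be non-negative")
    invisible(d)
}
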