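## File I/O: FASTQ/FASTA via Biostrings, tables as TSV, truth as JSON.

#' Read a FASTQ file into a read set
#'
#' @param path FASTQ file (Phred+33).
#' @return A [read_set()].
#' @export
read_fastq <- function(path) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    read_set(names(x), as.character(x),
             as.character(S4Vectors::mcols(x)$qualities))
}

#' Write a read set as FASTQ
#'
#' @param reads a [read_set()].
#' @param path output file.
#' @param append append to an existing file.
#' @export
write_fastq <- function(reads, path, append = FALSE) {
    reads <- as_read_set(reads)
    x <- Biostrings::DNAStringSet(reads$seq)
    names(x) <- reads$id
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(reads$qual),
                                append = append)
    invisible(path)
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector, or a [read_set()] (qualities dropped).
#' @param path output file.
#' @param append append to an existing file.
#' @export
write_fasta <- function(seqs, path, append = FALSE) {
    if (is.data.frame(seqs)) {
        x <- Biostrings::DNAStringSet(seqs$seq)
        names(x) <- seqs$id
    } else {
        x <- Biostrings::DNAStringSet(seqs)
        if (is.null(names(x))) names(x) <- sprintf("seq%06d", seq_along(x))
    }
    Biostrings::writeXStringSet(x, path, format = "fasta", append = append)
    invisible(path)
}

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
    x <- Biostrings::readDNAStringSet(path)
    stats::setNames(as.character(x), names(x))
}

ENV_UNITS <- c(pH = "pH", salinity = "g/L", TN = "g/kg", TOC = "%",
               sulfate = "g/L", MMT = "degC")

#' Write / read the environmental table
#'
#' One row per sample; a `# units:` comment line records the units. Values are
#' written at full double precision so the table round-trips losslessly.
#'
#' @param env data frame with a `sample_id` column plus numeric variables.
#' @param path TSV path.
#' @return `write_env_table` returns the path invisibly; `read_env_table`
#'   returns the data frame.
#' @export
write_env_table <- function(env, path) {
    stopifnot(is.data.frame(env), "sample_id" %in% names(env))
    vars <- setdiff(names(env), "sample_id")
    units <- ifelse(vars %in% names(ENV_UNITS), ENV_UNITS[vars], "unknown")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# units: ",
                      paste(vars, units, sep = "=", collapse = "; ")), con)
    out <- env
    for (v in vars) out[[v]] <- sprintf("%.17g", env[[v]])
    utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname write_env_table
#' @export
read_env_table <- function(path) {
    out <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
    out
}

#' Write / read a barcode table
#'
#' Columns: `sample_id`, `barcode`, `fwd_primer`, `rev_primer`.
#'
#' @param barcodes data frame with those columns.
#' @param path TSV path.
#' @export
write_barcode_table <- function(barcodes, path) {
    stopifnot(all(c("sample_id", "barcode", "fwd_primer", "rev_primer")
                  %in% names(barcodes)))
    utils::write.table(barcodes, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname write_barcode_table
#' @export
read_barcode_table <- function(path) {
    utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read the sample-to-lake table
#'
#' @param samples data frame with `sample_id` and `lake_id`.
#' @param path TSV path.
#' @export
write_sample_table <- function(samples, path) {
    stopifnot(all(c("sample_id", "lake_id") %in% names(samples)))
    utils::write.table(samples, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname write_sample_table
#' @export
read_sample_table <- function(path) {
    utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Serialize / restore planted ground truth as JSON
#'
#' @param truth an `epic_truth` object.
#' @param path JSON path.
#' @export
write_ground_truth <- function(truth, path) {
    stopifnot(inherits(truth, "epic_truth"))
    x <- list(lakes = truth$lakes, samples = truth$samples, otus = truth$otus,
              abundance = list(values = unname(truth$abundance),
                               sample_id = rownames(truth$abundance),
                               otu_id = colnames(truth$abundance)),
              presence_lake = list(values = unname(truth$presence_lake * 1L),
                                   lake_id = rownames(truth$presence_lake)),
              true_shannon = as.list(truth$true_shannon),
              env = truth$env)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
    invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    ab <- as.matrix(x$abundance$values)
    dimnames(ab) <- list(x$abundance$sample_id, x$abundance$otu_id)
    pres <- as.matrix(x$presence_lake$values) == 1
    dimnames(pres) <- list(x$presence_lake$lake_id, x$abundance$otu_id)
    structure(list(design = NULL, lakes = x$lakes, samples = x$samples,
                   otus = x$otus, abundance = ab, presence_lake = pres,
                   true_shannon = unlist(x$true_shannon), env = x$env),
              class = "epic_truth")
}
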