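## End-to-end convenience: raw FASTQ pairs -> joint OTU table.

#' Run the full epicPCR + bulk 16S pipeline
#'
#' Processes both libraries (demultiplex, primer trim, merge, split for the
#' fused library, windowed quality filter), pools the 16S streams, clusters
#' them into a joint OTU table, and optionally rarefies it.
#'
#' @param fused,bulk each a `list(r1, r2)` of [read_set()]s or FASTQ paths
#'   (as returned by [synthesize_reads()]).
#' @param barcodes_fused,barcodes_bulk barcode tables (data frames with
#'   `sample_id`, `barcode`, `fwd_primer`, `rev_primer`) or TSV paths.
#' @param split a [split_rule()] for the fused library.
#' @param filter a [filter_rule()].
#' @param cluster a [cluster_params()].
#' @param min_overlap minimum pair overlap for merging.
#' @param rarefy_depth if non-NULL, rarefy the table to this depth.
#' @param seed seed for the rarefaction draw.
#' @return List with `table` (the `otu_table`), `report_fused`,
#'   `report_bulk` (stage reports) and `pool` (the labelled sequence pool).
#' @export
run_epicpcr_pipeline <- function(fused, bulk, barcodes_fused, barcodes_bulk,
                                 split = split_rule(),
                                 filter = filter_rule(),
                                 cluster = cluster_params(),
                                 min_overlap = 30,
                                 rarefy_depth = NULL, seed = 1L) {
    if (is.character(barcodes_fused))
        barcodes_fused <- read_barcode_table(barcodes_fused)
    if (is.character(barcodes_bulk))
        barcodes_bulk <- read_barcode_table(barcodes_bulk)
    pf <- process_fused_reads(fused$r1, fused$r2, barcodes_fused,
                              split = split, filter = filter,
                              min_overlap = min_overlap)
    pb <- process_bulk_reads(bulk$r1, bulk$r2, barcodes_bulk,
                             filter = filter, min_overlap = min_overlap)
    pool <- combine_streams(pf$ssu, pb$ssu,
                            samples = barcodes_bulk$sample_id)
    table <- cluster_pool(pool, cluster)
    if (!is.null(rarefy_depth))
        table <- rarefy_table(table, depth = rarefy_depth, seed = seed)
    list(table = table, report_fused = pf$report, report_bulk = pb$report,
         pool = pool, dsrb = pf$dsrb)
}
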