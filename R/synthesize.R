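## Synthetic read generation from planted ground truth.

## Sample barcodes with pairwise Hamming distance >= min_dist (demultiplexing
## with max_mismatch = 1 requires distance > 2).
generate_barcodes <- function(n, len, min_dist = 3) {
    out <- character(0)
    tries <- 0
    while (length(out) < n) {
        cand <- random_dna(1, len)
        ok <- TRUE
        if (length(out)) {
            d <- cpp_hamming(rep(cand, length(out)), out)
            ok <- all(d >= min_dist)
        }
        if (ok) out <- c(out, cand)
        tries <- tries + 1
        if (tries > 2000 * n)
            stop("could not generate ", n, " barcodes of length ", len,
                 " at pairwise distance >= ", min_dist)
    }
    out
}

## Two-parent, single-breakpoint chimeric 16S fragments. Parents are the two
## most abundant eligible taxa in the sample (so the abundance-skew screen can
## catch the children); breakpoints are uniform with a 40 bp margin.
make_chimeric_16s <- function(n, seq_a, seq_b, margin = 40) {
    la <- nchar(seq_a); lb <- nchar(seq_b)
    lo <- margin
    hi <- min(la, lb) - margin
    if (n == 0) return(character())
    if (hi <= lo)
        stop("templates too short for chimera breakpoints with this margin")
    b <- sample(lo:hi, n, replace = TRUE)
    paste0(substr(rep(seq_a, n), 1, b), substr(rep(seq_b, n), b + 1, lb))
}

## Build one library's raw read pairs for one sample.
## insert: character vector of per-read insert sequences (already chimera-
## substituted). Returns list(r1 = read_set, r2 = read_set).
build_pairs <- function(inserts, ids, barcode, fwd_primer, rev_primer, layout) {
    n <- length(inserts)
    if (n == 0) return(list(r1 = empty_read_set(), r2 = empty_read_set()))
    L <- nchar(inserts)
    rl <- layout$read_len
    if (any(L < rl))
        stop("insert shorter than read_len; layout cannot produce these reads")
    fwdp <- resolve_iupac(fwd_primer, n)
    revp <- resolve_iupac(rev_primer, n)
    r1 <- paste0(barcode, fwdp, substr(inserts, 1, rl))
    r2 <- paste0(revp, revcomp(substr(inserts, L - rl + 1, L)))

    q35 <- intToUtf8(layout$base_q + 33L)
    q10 <- intToUtf8(layout$tail_q + 33L)
    q1 <- strrep(q35, nchar(r1))
    q2 <- strrep(q35, nchar(r2))
    ## low-quality tails: degrade the start of the reverse read's insert
    ## portion (it maps to the merged fragment's 3' end, which is where the
    ## windowed filter will see it)
    n_tail <- sum(stats::runif(n) < layout$lowq_tail_frac)
    if (n_tail > 0) {
        idx <- sample.int(n, n_tail)
        k <- sample(layout$tail_len[1]:layout$tail_len[2], n_tail,
                    replace = TRUE)
        plen <- nchar(revp[idx])
        q2[idx] <- paste0(strrep(q35, plen), strrep(q10, k),
                          strrep(q35, nchar(r2[idx]) - plen - k))
    }
    list(r1 = read_set(ids, r1, q1), r2 = read_set(paste0(ids, "/2"), r2, q2))
}

#' Synthesize fused (epicPCR) and bulk 16S read pairs
#'
#' Emits, per sample, `depth_per_sample` read pairs for each library. Bulk
#' reads sample every planted taxon; fused reads sample only SRP-flagged taxa
#' (the epicPCR library sees the functional sub-community). Read counts per
#' taxon are apportioned to the planted relative abundances by largest
#' remainder ("exact" mode) or drawn multinomially. A `chimera_rate` fraction
#' of each sample's reads is replaced by two-parent single-breakpoint
#' chimeras; substitution errors are injected at `per_base_error` per base
#' using an RNG stream derived from `seed` but separate from the structural
#' draws, so the same seed with different error rates yields positionally
#' comparable reads.
#'
#' @param truth an `epic_truth` from [design_community()].
#' @param layout a [read_layout()].
#' @param depth_per_sample read pairs per sample and library.
#' @param seed integer seed; identical seeds give byte-identical FASTQ.
#' @param sampling `"exact"` (largest-remainder apportionment; planted
#'   presence is recovered deterministically) or `"multinomial"`.
#' @param outdir if non-NULL, FASTQ pairs and barcode tables are written here.
#' @return List with `fused` and `bulk` (each `list(r1, r2)` of
#'   [read_set()]s), `barcodes_fused`, `barcodes_bulk` (barcode tables), and
#'   `paths` when `outdir` was given.
#' @export
synthesize_reads <- function(truth, layout = read_layout(),
                             depth_per_sample = 15000, seed = 1L,
                             sampling = c("exact", "multinomial"),
                             outdir = NULL) {
    stopifnot(inherits(truth, "epic_truth"), inherits(layout, "read_layout"))
    sampling <- match.arg(sampling)
    if (depth_per_sample <= 0) stop("depth_per_sample must be positive")
    otus <- truth$otus
    if (any(nchar(otus$seq16s[otus$srp]) + layout$dsrb_len +
            nchar(layout$bridge_primer) > 2 * layout$read_len - 30) ||
        any(nchar(otus$seq16s) > 2 * layout$read_len - 30))
        stop("layout cannot produce the declared merged lengths: read pairs ",
             "would overlap by fewer than 30 bases")
    if (any(nchar(otus$dsrb[otus$srp]) != layout$dsrb_len))
        stop("layout dsrb_len does not match the planted dsrB templates")

    set.seed(as.integer(seed))
    samples <- truth$samples$sample_id
    n_samp <- length(samples)
    barcodes <- generate_barcodes(n_samp, layout$barcode_len)
    names(barcodes) <- samples

    srp_idx <- which(otus$srp)
    fused <- list(r1 = vector("list", n_samp), r2 = vector("list", n_samp))
    bulk <- list(r1 = vector("list", n_samp), r2 = vector("list", n_samp))

    one_library <- function(s, taxa, lib) {
        ab <- truth$abundance[s, taxa]
        if (sum(ab) == 0)
            stop("sample ", s, " has no eligible taxa for the ", lib,
                 " library")
        n_chim <- round(depth_per_sample * layout$chimera_rate)
        ## chimeras need two abundant parents; degenerate samples (a single
        ## eligible taxon) emit real reads only
        if (length(taxa) < 2 || sort(ab, decreasing = TRUE)[2] == 0)
            n_chim <- 0
        n_real <- depth_per_sample - n_chim
        counts <- if (sampling == "exact") alloc_counts(ab, n_real)
                  else as.integer(stats::rmultinom(1, n_real, ab))
        tpl <- rep(taxa, counts)
        ssu <- otus$seq16s[tpl]
        if (n_chim > 0) {
            top2 <- taxa[order(ab, decreasing = TRUE)[1:2]]
            chim <- make_chimeric_16s(n_chim, otus$seq16s[top2[1]],
                                      otus$seq16s[top2[2]])
            ssu <- c(ssu, chim)
            tpl <- c(tpl, rep(top2[1], n_chim))  # dsrB side follows parent A
        }
        if (lib == "fused") {
            bridge <- resolve_iupac(layout$bridge_primer, length(ssu))
            inserts <- paste0(otus$dsrb[tpl], bridge, ssu)
            build_pairs(inserts,
                        sprintf("%s_fused_%07d", s, seq_along(inserts)),
                        barcodes[[s]], layout$fused_fwd_primer,
                        layout$fused_rev_primer, layout)
        } else {
            build_pairs(ssu, sprintf("%s_bulk_%07d", s, seq_along(ssu)),
                        barcodes[[s]], layout$fwd_primer, layout$rev_primer,
                        layout)
        }
    }

    for (i in seq_len(n_samp)) {
        s <- samples[i]
        present <- which(truth$abundance[s, ] > 0)
        pf <- one_library(s, intersect(present, srp_idx), "fused")
        pb <- one_library(s, present, "bulk")
        fused$r1[[i]] <- pf$r1; fused$r2[[i]] <- pf$r2
        bulk$r1[[i]] <- pb$r1; bulk$r2[[i]] <- pb$r2
    }
    bind <- function(lst) {
        out <- do.call(rbind, lst)
        rownames(out) <- NULL
        class(out) <- c("read_set", "data.frame")
        out
    }
    fused <- list(r1 = bind(fused$r1), r2 = bind(fused$r2))
    bulk <- list(r1 = bind(bulk$r1), r2 = bind(bulk$r2))

    ## error injection on its own RNG stream (structure stays comparable
    ## across error rates at a fixed seed)
    if (layout$per_base_error > 0) {
        set.seed(as.integer(seed) + 1009L)
        fused$r1$seq <- cpp_inject_errors(fused$r1$seq, layout$per_base_error)
        fused$r2$seq <- cpp_inject_errors(fused$r2$seq, layout$per_base_error)
        bulk$r1$seq <- cpp_inject_errors(bulk$r1$seq, layout$per_base_error)
        bulk$r2$seq <- cpp_inject_errors(bulk$r2$seq, layout$per_base_error)
    }

    bc_tbl <- function(fwd, rev) data.frame(
        sample_id = samples, barcode = unname(barcodes),
        fwd_primer = fwd, rev_primer = rev, stringsAsFactors = FALSE)
    out <- list(fused = fused, bulk = bulk,
                barcodes_fused = bc_tbl(layout$fused_fwd_primer,
                                        layout$fused_rev_primer),
                barcodes_bulk = bc_tbl(layout$fwd_primer, layout$rev_primer))

    if (!is.null(outdir)) {
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        paths <- list(
            fused_r1 = file.path(outdir, "fused_R1.fastq"),
            fused_r2 = file.path(outdir, "fused_R2.fastq"),
            bulk_r1 = file.path(outdir, "bulk_R1.fastq"),
            bulk_r2 = file.path(outdir, "bulk_R2.fastq"),
            barcodes_fused = file.path(outdir, "barcodes_fused.tsv"),
            barcodes_bulk = file.path(outdir, "barcodes_bulk.tsv"))
        write_fastq(out$fused$r1, paths$fused_r1)
        write_fastq(out$fused$r2, paths$fused_r2)
        write_fastq(out$bulk$r1, paths$bulk_r1)
        write_fastq(out$bulk$r2, paths$bulk_r2)
        write_barcode_table(out$barcodes_fused, paths$barcodes_fused)
        write_barcode_table(out$barcodes_bulk, paths$barcodes_bulk)
        out$paths <- paths
    }
    out
}

#' Simulate a complete synthetic study on disk
#'
#' Convenience wrapper: draws the planted truth, synthesizes both libraries,
#' and writes FASTQ pairs, barcode tables, the sample-to-lake table, the
#' environmental table and the ground-truth JSON into `outdir`.
#'
#' @inheritParams synthesize_reads
#' @param design a [community_design()].
#' @param outdir output directory (created if needed).
#' @return Invisibly, a list with the `truth` and all file `paths`.
#' @export
simulate_epicpcr <- function(design = community_design(),
                             layout = read_layout(),
                             depth_per_sample = 15000, seed = 1L,
                             outdir) {
    truth <- design_community(design, seed = seed)
    sim <- synthesize_reads(truth, layout, depth_per_sample,
                            seed = seed, outdir = outdir)
    paths <- sim$paths
    paths$samples <- file.path(outdir, "samples.tsv")
    paths$env <- file.path(outdir, "env.tsv")
    paths$truth <- file.path(outdir, "ground_truth.json")
    write_sample_table(truth$samples, paths$samples)
    write_env_table(truth$env, paths$env)
    write_ground_truth(truth, paths$truth)
    invisible(list(truth = truth, paths = paths))
}
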