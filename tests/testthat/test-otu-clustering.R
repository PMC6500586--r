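test_that("stream pooling preserves provenance and conserves reads", {
    epic <- list(S1 = c("AAAA", "CCCC"), S2 = character(0))
    bulk <- list(S1 = c("GGGG"), S2 = c("TTTT", "AAAA", "CCCC"))
    pool <- combine_streams(epic, bulk)
    expect_identical(nrow(pool), 6L)
    expect_identical(sum(pool$source == "epic"), 2L)
    expect_identical(sum(pool$source == "bulk"), 4L)
    ## S2 contributes bulk reads only
    expect_true(all(pool$source[pool$sample_id == "S2"] == "bulk"))
    expect_error(combine_streams(epic, bulk, samples = "S1"), "unknown sample")
})

test_that("dereplication counts, sorts and tie-breaks deterministically", {
    pool <- data.frame(sample_id = "S1", source = "bulk",
                       seq = c(rep("CCCC", 3), rep("AAAA", 3), "TTTT"),
                       stringsAsFactors = FALSE)
    dr <- dereplicate(pool)
    expect_identical(dr$uniques$seq, c("AAAA", "CCCC", "TTTT"))  # tie: lexicographic
    expect_identical(dr$uniques$abundance, c(3L, 3L, 1L))
    expect_identical(sum(dr$uniques$abundance), nrow(pool))
    expect_identical(dr$uniques$seq[dr$map], pool$seq)
    ## all-identical and all-distinct degenerate pools
    expect_identical(dereplicate(rep("ACGT", 10))$uniques$abundance, 10L)
    dist10 <- fixture_dna(10, 20, seed = 1)
    expect_identical(dereplicate(dist10)$uniques$abundance, rep(1L, 10))
})

test_that("identity threshold admits exactly 97% and splits at 96%", {
    base <- fixture_dna(1, 100, seed = 2)
    u3 <- data.frame(seq = c(base, mutate_seq(base, 3, seed = 3)),
                     abundance = c(5L, 1L), stringsAsFactors = FALSE)
    cl3 <- greedy_cluster(u3, cluster_params())
    expect_identical(length(cl3$otu_ids), 1L)  # 97/100 >= 0.97
    u4 <- data.frame(seq = c(base, mutate_seq(base, 4, seed = 4)),
                     abundance = c(5L, 1L), stringsAsFactors = FALSE)
    cl4 <- greedy_cluster(u4, cluster_params())
    expect_identical(length(cl4$otu_ids), 2L)  # 96/100 < 0.97
})

test_that("pairwise identity agrees with the DP oracle", {
    set.seed(5)
    base <- fixture_dna(3, c(70, 80, 74), seed = 5)
    seqs <- c(base[1],
              mutate_seq(base[1], 2, seed = 6),       # substitutions
              substr(base[1], 1, 64),                 # truncation
              paste0("ACG", base[1]),                 # extension
              base[2], mutate_seq(base[2], 5, seed = 7),
              base[3])
    pairs <- combn(length(seqs), 2)
    for (k in seq_len(ncol(pairs))) {
        a <- seqs[pairs[1, k]]; b <- seqs[pairs[2, k]]
        expect_equal(sequence_identity(a, b), oracle_identity(a, b),
                     tolerance = 1e-12,
                     info = sprintf("pair %d-%d", pairs[1, k], pairs[2, k]))
    }
})

test_that("greedy clustering partition equals the brute-force oracle", {
    ## 20 sequences: 5 planted centers with substitution variants at several
    ## distances around the 97% boundary, plus unrelated singletons
    centers <- fixture_dna(5, 80, seed = 8)
    seqs <- c(centers[1], mutate_seq(centers[1], 1, seed = 9),
              mutate_seq(centers[1], 2, seed = 10),
              centers[2], mutate_seq(centers[2], 2, seed = 11),
              mutate_seq(centers[2], 3, seed = 12),   # 77/80 = 0.9625 -> new
              centers[3], mutate_seq(centers[3], 1, seed = 13),
              centers[4], mutate_seq(centers[4], 4, seed = 14),
              centers[5],
              fixture_dna(9, 80, seed = 15))
    abund <- c(20, 6, 5, 18, 6, 5, 15, 4, 12, 3, 10, 9:1)
    ord <- order(-abund, seqs)
    uniq <- data.frame(seq = seqs[ord], abundance = as.integer(abund[ord]),
                       stringsAsFactors = FALSE)
    cl <- greedy_cluster(uniq, cluster_params())
    oracle <- oracle_greedy(uniq$seq)
    expect_identical(cl$otu, oracle)
    ## representatives are the founders (most abundant members)
    founders <- tapply(seq_len(nrow(uniq)), cl$otu, min)
    expect_identical(unname(cl$representatives),
                     uniq$seq[as.integer(founders)])
})

test_that("chimera screen catches planted two-parent splices", {
    pa <- fixture_dna(1, 200, seed = 16)
    pb <- fixture_dna(1, 200, seed = 17)
    chim <- paste0(substr(pa, 1, 90), substr(pb, 91, 200))
    uniq <- data.frame(seq = c(pa, pb, chim),
                       abundance = c(50L, 30L, 2L), stringsAsFactors = FALSE)
    cs <- chimera_screen(uniq, cluster_params())
    expect_identical(cs$flagged$seq, chim)
    ## an ordinary point-error read of pa is NOT flagged
    var1 <- mutate_seq(pa, 1, seed = 18)
    uniq2 <- data.frame(seq = c(pa, pb, var1),
                        abundance = c(50L, 30L, 1L), stringsAsFactors = FALSE)
    expect_identical(nrow(chimera_screen(uniq2, cluster_params())$flagged), 0L)
    ## abundance skew matters: child at half the parent abundance escapes
    uniq3 <- data.frame(seq = c(pa, pb, chim),
                        abundance = c(3L, 3L, 2L), stringsAsFactors = FALSE)
    expect_identical(nrow(chimera_screen(uniq3, cluster_params())$flagged), 0L)
})

test_that("chimera flags equal the exhaustive triple-scan oracle", {
    set.seed(19)
    parents <- fixture_dna(6, 150, seed = 19)
    mk_chim <- function(a, b, bp) paste0(substr(parents[a], 1, bp),
                                         substr(parents[b], bp + 1, 150))
    seqs <- c(parents,
              mk_chim(1, 2, 75), mk_chim(3, 4, 50), mk_chim(5, 6, 110),
              mk_chim(2, 1, 40),
              vapply(1:4, function(i) mutate_seq(parents[i], 1, seed = 20 + i),
                     character(1)),
              fixture_dna(16, 150, seed = 25))
    abund <- c(60L, 55L, 50L, 45L, 40L, 35L,
               rep(2L, 4), rep(3L, 4), rep(1L, 16))
    ord <- order(-abund, seqs)
    uniq <- data.frame(seq = seqs[ord], abundance = abund[ord],
                       stringsAsFactors = FALSE)
    cs <- chimera_screen(uniq, cluster_params())
    oracle_flags <- oracle_chimera(uniq$seq, uniq$abundance)
    expect_identical(uniq$seq %in% cs$flagged$seq, oracle_flags)
    ## zero chimera rate in the generator -> zero flags downstream
    truth <- design_community(community_design(n_lakes = 3,
                                               samples_per_lake = c(2, 2, 2),
                                               frac_ubiquitous = 0.1,
                                               n_otus = 15), seed = 26)
    lay <- read_layout(per_base_error = 0.003, chimera_rate = 0,
                       lowq_tail_frac = 0)
    sim <- synthesize_reads(truth, lay, depth_per_sample = 100, seed = 26)
    res <- run_epicpcr_pipeline(sim$fused, sim$bulk, sim$barcodes_fused,
                                sim$barcodes_bulk)
    expect_identical(sum(res$table$n_chimera), 0L)
})

test_that("every pooled read lands in exactly one OTU or the chimera bin", {
    truth <- design_community(community_design(n_lakes = 3,
                                               samples_per_lake = c(2, 2, 2),
                                               frac_ubiquitous = 0.1,
                                               n_otus = 15), seed = 27)
    sim <- synthesize_reads(truth, read_layout(), depth_per_sample = 120,
                            seed = 27)
    res <- run_epicpcr_pipeline(sim$fused, sim$bulk, sim$barcodes_fused,
                                sim$barcodes_bulk)
    expect_identical(sum(res$table$counts) + sum(res$table$n_chimera),
                     nrow(res$pool))
    expect_identical(res$table$counts,
                     res$table$counts_epic + res$table$counts_bulk)
    ## provenance counts round-trip to the pool, per sample
    for (s in rownames(res$table$counts)) {
        in_pool <- res$pool$sample_id == s
        expect_identical(sum(res$table$counts[s, ]) + res$table$n_chimera[[s]],
                         sum(in_pool))
        expect_lte(sum(res$table$counts_epic[s, ]),
                   sum(in_pool & res$pool$source == "epic"))
    }
})

test_that("noisy OTU counts stay in a narrow band of rare extras", {
    truth <- design_community(community_design(n_lakes = 4,
                                               samples_per_lake = c(3, 2, 2, 2),
                                               n_otus = 30), seed = 28)
    ## substitution noise alone: every planted taxon is recovered; a rare
    ## taxon whose few reads all carry errors can split into one extra rare
    ## OTU (no error-free read exists to anchor the cluster), so the count
    ## sits in a narrow band above n_otus and the extras are all singletons
    ## or doubletons
    lay_sub <- read_layout(per_base_error = 0.005, chimera_rate = 0,
                           lowq_tail_frac = 0.02)
    sim <- synthesize_reads(truth, lay_sub, depth_per_sample = 150, seed = 28)
    res <- run_epicpcr_pipeline(sim$fused, sim$bulk, sim$barcodes_fused,
                                sim$barcodes_bulk)
    tab1 <- annotate_otus(res$table, truth)
    expect_identical(length(unique(na.omit(tab1$taxonomy$planted_taxon))),
                     30L)
    expect_gte(ncol(res$table$counts), 30L)
    expect_lte(ncol(res$table$counts), 34L)
    ## the extras (beyond one dominant OTU per planted taxon) are all rare
    tx1 <- tab1$taxonomy
    sz1 <- colSums(tab1$counts)
    dominant <- tapply(seq_along(sz1), tx1$planted_taxon,
                       function(ix) ix[which.max(sz1[ix])])
    extras <- setdiff(seq_along(sz1), unlist(dominant))
    expect_true(all(sz1[extras] <= 2))
    ## with chimeras, spurious OTUs are error-bearing escaped chimeras:
    ## all rare, and every planted taxon is still recovered
    lay_full <- read_layout()
    sim2 <- synthesize_reads(truth, lay_full, depth_per_sample = 150,
                             seed = 28)
    res2 <- run_epicpcr_pipeline(sim2$fused, sim2$bulk, sim2$barcodes_fused,
                                 sim2$barcodes_bulk)
    tab2 <- annotate_otus(res2$table, truth)
    matched <- !is.na(tab2$taxonomy$planted_taxon)
    expect_identical(length(unique(tab2$taxonomy$planted_taxon[matched])),
                     30L)
    spur_sizes <- colSums(tab2$counts)[!matched]
    expect_true(all(spur_sizes <= 2))
    n_planted_chim <- round(150 * lay_full$chimera_rate) * 9 * 2
    expect_lte(ncol(res2$table$counts), 30L + n_planted_chim)
})

test_that("rarefaction normalizes depths, drops shallow samples, reproduces", {
    counts <- matrix(c(40L, 30L, 20L, 10L,
                       100L, 0L, 0L, 0L,
                       5L, 2L, 1L, 1L), 3, 4, byrow = TRUE,
                     dimnames = list(c("A", "B", "C"), paste0("o", 1:4)))
    tab <- structure(list(counts = counts, counts_epic = counts * 0L,
                          counts_bulk = counts,
                          representatives = setNames(fixture_dna(4, 30,
                                                                 seed = 29),
                                                     paste0("o", 1:4)),
                          n_chimera = setNames(c(0L, 0L, 0L),
                                               rownames(counts)),
                          taxonomy = NULL),
                     class = "otu_table")
    expect_warning(r <- rarefy_table(tab, depth = 100, seed = 1), "dropped")
    expect_identical(rownames(r$counts), c("A", "B"))
    expect_true(all(rowSums(r$counts) == 100))
    ## sampling all reads leaves counts unchanged
    expect_identical(r$counts["A", ], counts["A", ])
    ## deterministic given seed
    r2 <- suppressWarnings(rarefy_table(tab, depth = 60, seed = 7))
    r3 <- suppressWarnings(rarefy_table(tab, depth = 60, seed = 7))
    expect_identical(r2$counts, r3$counts)
    ## everything below depth -> error
    expect_error(suppressWarnings(rarefy_table(tab, depth = 1000)),
                 "below the rarefaction depth")
})

test_that("rarefied counts match the hypergeometric expectation", {
    counts <- matrix(c(40L, 30L, 20L, 10L), 1,
                     dimnames = list("A", paste0("o", 1:4)))
    tab <- structure(list(counts = counts, counts_epic = counts * 0L,
                          counts_bulk = counts,
                          representatives = setNames(fixture_dna(4, 30,
                                                                 seed = 30),
                                                     paste0("o", 1:4)),
                          n_chimera = setNames(0L, "A"), taxonomy = NULL),
                     class = "otu_table")
    draws <- vapply(1:200, function(s)
        rarefy_table(tab, depth = 50, seed = s)$counts[1, ], numeric(4))
    m <- rowMeans(draws)
    expected <- 50 * counts[1, ] / 100
    N <- 100; d <- 50
    vr <- d * (counts[1, ] / N) * (1 - counts[1, ] / N) * (N - d) / (N - 1)
    se <- sqrt(vr / 200)
    expect_true(all(abs(m - expected) <= 3 * se + 1e-9))
})

test_that("OTU tables round-trip through TSV plus representative FASTA", {
    truth <- design_community(community_design(n_lakes = 3,
                                               samples_per_lake = c(2, 2, 2),
                                               frac_ubiquitous = 0.1,
                                               n_otus = 10), seed = 31)
    lay <- read_layout(per_base_error = 0, chimera_rate = 0,
                       lowq_tail_frac = 0)
    sim <- synthesize_reads(truth, lay, depth_per_sample = 50, seed = 31)
    res <- run_epicpcr_pipeline(sim$fused, sim$bulk, sim$barcodes_fused,
                                sim$barcodes_bulk)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_otu_table(res$table, path)
    back <- read_otu_table(path)
    expect_identical(back$counts, res$table$counts)
    expect_identical(unname(back$representatives),
                     unname(res$table$representatives))
})
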