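bc2 <- c(S1 = "AAAAAAAA", S2 = "TTTTTTTT")

test_that("demultiplexing assigns exact and 1-mismatch barcodes, not ties", {
    rule <- demux_rule(bc2, max_mismatch = 1)
    reads <- read_set(
        c("exact", "one_mm", "two_mm", "other"),
        c(paste0("AAAAAAAA", "ACGT"), paste0("AAAAAAAT", "ACGT"),
          paste0("AAAAAATT", "ACGT"), paste0("TTTTTTTT", "GGCC")),
        strrep("I", c(12, 12, 12, 12)))
    dm <- demultiplex(reads, rule)
    expect_identical(dm$samples$S1$id, c("exact", "one_mm"))
    expect_identical(dm$samples$S1$seq, c("ACGT", "ACGT"))  # barcode stripped
    expect_identical(dm$samples$S2$id, "other")
    expect_identical(dm$unassigned$id, "two_mm")
    ## ambiguous table rejected at construction
    expect_error(demux_rule(c(a = "AAAA", b = "AAAT")), "ambiguous")
})

test_that("demultiplexing agrees with a brute-force Hamming scan", {
    truth <- design_community(community_design(), seed = 7)
    sim <- synthesize_reads(truth, read_layout(), depth_per_sample = 40,
                            seed = 7)
    rule <- demux_rule(sim$barcodes_bulk, max_mismatch = 1)
    dm <- demultiplex(sim$bulk$r1, rule)
    bl <- nchar(rule$barcodes[[1]])
    expected <- vapply(sim$bulk$r1$seq, function(s) {
        d <- vapply(unname(rule$barcodes),
                    function(b) oracle_hamming(substr(s, 1, bl), b),
                    numeric(1))
        hits <- which(d <= 1)
        if (length(hits) == 1) names(rule$barcodes)[hits] else "(un)"
    }, character(1), USE.NAMES = FALSE)
    got_counts <- vapply(dm$samples, nrow, integer(1))
    exp_counts <- table(factor(expected,
                               levels = c(names(rule$barcodes), "(un)")))
    expect_identical(unname(got_counts),
                     as.integer(exp_counts[names(dm$samples)]))
    expect_identical(nrow(dm$unassigned), as.integer(exp_counts[["(un)"]]))
})

test_that("demultiplexing is invariant to read order", {
    truth <- design_community(community_design(n_lakes = 3,
                                               samples_per_lake = c(2, 2, 2),
                                               frac_ubiquitous = 0.1,
                                               n_otus = 15), seed = 8)
    sim <- synthesize_reads(truth, read_layout(), depth_per_sample = 50,
                            seed = 8)
    rule <- demux_rule(sim$barcodes_bulk)
    dm1 <- demultiplex(sim$bulk$r1, rule)
    set.seed(1)
    shuf <- sim$bulk$r1[sample(nrow(sim$bulk$r1)), ]
    dm2 <- demultiplex(epicflow::read_set(shuf$id, shuf$seq, shuf$qual), rule)
    expect_identical(vapply(dm1$samples, nrow, integer(1)),
                     vapply(dm2$samples, nrow, integer(1)))
})

test_that("primer trimming honors IUPAC degeneracy with one mismatch", {
    p515 <- "GTGCCAGCMGCCGCGGTAA"
    body <- strrep("ACGT", 20)
    reads <- read_set(
        c("m_as_a", "m_as_c", "one_mm", "two_mm", "no_primer"),
        c(paste0("GTGCCAGCAGCCGCGGTAA", body),
          paste0("GTGCCAGCCGCCGCGGTAA", body),
          paste0("TTGCCAGCAGCCGCGGTAA", body),
          paste0("TTGACAGCAGCCGCGGTAA", body),
          paste0(strrep("T", 19), body)),
        strrep("I", rep(19 + 80, 5)))
    tr <- trim_primer(reads, p515, max_mismatch = 1)
    expect_identical(tr$kept$id, c("m_as_a", "m_as_c", "one_mm"))
    expect_true(all(tr$kept$seq == body))
    expect_identical(tr$rejected$id, c("two_mm", "no_primer"))
    ## H matches A/C/T, V matches A/C/G, W matches A/T
    r806 <- "GGACTACHVGGGTWTCTAAT"
    hits <- c("GGACTACTAGGGTATCTAAT", "GGACTACCGGGGTTTCTAAT",
              "GGACTACAVGGGTWTCTAAT")
    tr2 <- trim_primer(read_set(letters[1:3], paste0(hits, body),
                                strrep("I", nchar(hits) + 80)), r806, 0)
    expect_identical(nrow(tr2$kept), 2L)  # literal V/W in read are not bases
})

test_that("planted 1-mismatch primers are all trimmed", {
    p <- "GTGCCAGCMGCCGCGGTAA"
    set.seed(31)
    inst <- epicflow:::resolve_iupac(p, 1000)
    inst1 <- vapply(inst, mutate_seq, character(1), k = 1,
                    seed = sample.int(1e6, 1), USE.NAMES = FALSE)
    body <- fixture_dna(1000, 50, seed = 32)
    tr <- trim_primer(read_set(sprintf("r%04d", 1:1000),
                               paste0(inst1, body),
                               rep(strrep("I", nchar(p) + 50), 1000)), p, 1)
    expect_identical(nrow(tr$kept), 1000L)
    expect_identical(tr$kept$seq, body)
})

test_that("pair merging finds the exact overlap and respects the minimum", {
    insert <- fixture_dna(1, 283, seed = 40)
    ## 160 + 160 with a 37-base overlap -> 283-bp merged fragment
    f <- substr(insert, 1, 160)
    r <- substr(insert, 124, 283)
    rc <- function(x) as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(x)))
    fwd <- read_set("p1", f, strrep("I", 160))
    rev <- read_set("p1/2", rc(r), strrep("I", 160))
    mg <- merge_pairs(fwd, rev, min_overlap = 30)
    expect_identical(nrow(mg$merged), 1L)
    expect_identical(nchar(mg$merged$seq), 283L)
    expect_identical(mg$merged$seq, insert)
    ## a 29-base overlap is below the minimum -> rejected
    insert2 <- fixture_dna(1, 291, seed = 41)
    fwd2 <- read_set("p2", substr(insert2, 1, 160), strrep("I", 160))
    rev2 <- read_set("p2/2", rc(substr(insert2, 132, 291)), strrep("I", 160))
    mg2 <- merge_pairs(fwd2, rev2, min_overlap = 30)
    expect_identical(nrow(mg2$merged), 0L)
    expect_identical(mg2$rejected$id, "p2")
})

test_that("noisy merging equals the all-offset scoring oracle", {
    set.seed(43)
    for (k in 1:25) {
        insert <- fixture_dna(1, sample(250:300, 1), seed = 430 + k)
        L <- nchar(insert)
        f <- substr(insert, 1, 165)
        r <- substr(insert, L - 164, L)
        ## inject a few substitutions into each mate
        f <- mutate_seq(f, sample(0:3, 1), seed = 5000 + k)
        r <- mutate_seq(r, sample(0:3, 1), seed = 6000 + k)
        fq <- intToUtf8(sample(25:40, 165, replace = TRUE) + 33L)
        rq <- intToUtf8(sample(25:40, 165, replace = TRUE) + 33L)
        rc <- function(x) as.character(
            Biostrings::reverseComplement(Biostrings::DNAString(x)))
        got <- merge_pairs(read_set("x", f, fq),
                           read_set("x/2", rc(r),
                                    paste(rev(strsplit(rq, "")[[1]]),
                                          collapse = "")),
                           min_overlap = 30)
        exp <- oracle_merge(f, fq, r, rq)
        if (is.null(exp)) {
            expect_identical(nrow(got$merged), 0L)
        } else {
            expect_identical(got$merged$seq, exp$seq)
            expect_identical(got$merged$qual, exp$qual)
        }
    }
})

test_that("fused reads split into a 30-bp dsrB and the 16S fragment", {
    bridge <- "GWATTACCGCGGCKGCTG"
    binst <- "GAATTACCGCGGCTGCTG"
    dsrb <- fixture_dna(1, 30, seed = 50)
    ssu <- fixture_dna(1, 253, seed = 51)
    merged <- read_set("f1", paste0(dsrb, binst, ssu),
                       strrep("I", 30 + 18 + 253))
    sp <- split_fused(merged, split_rule(30, bridge, 2))
    expect_identical(sp$dsrb$seq, dsrb)
    expect_identical(nchar(sp$dsrb$seq), 30L)
    expect_identical(sp$ssu$seq, ssu)
    expect_identical(nchar(sp$ssu$seq), 253L)
    expect_identical(sp$ssu$id, "f1")
    ## too short to contain prefix + bridge -> rejected
    short <- read_set("f2", substr(paste0(dsrb, binst), 1, 40), strrep("I", 40))
    sp2 <- split_fused(short, split_rule(30, bridge, 2))
    expect_identical(nrow(sp2$ssu), 0L)
    expect_identical(sp2$rejected$id, "f2")
    ## bridge beyond the mismatch budget -> rejected, counted separately
    bad <- read_set("f3", paste0(dsrb, mutate_seq(binst, 3, seed = 52), ssu),
                    strrep("I", 301))
    sp3 <- split_fused(bad, split_rule(30, bridge, 2))
    expect_identical(sp3$rejected$id, "f3")
})

test_that("split success rate tracks planted bridge errors", {
    bridge <- "GAATTACCGCGGCTGCTG"  # concrete bridge: mismatches controlled
    n <- 400
    dsrb <- fixture_dna(n, 30, seed = 53)
    ssu <- fixture_dna(n, 250, seed = 54)
    set.seed(55)
    k_err <- sample(0:4, n, replace = TRUE)
    binst <- vapply(seq_len(n), function(i)
        if (k_err[i] == 0) bridge else mutate_seq(bridge, k_err[i],
                                                  seed = 600 + i),
        character(1))
    reads <- read_set(sprintf("r%03d", 1:n), paste0(dsrb, binst, ssu),
                      rep(strrep("I", 298), n))
    sp <- split_fused(reads, split_rule(30, bridge, 2))
    expect_identical(nrow(sp$ssu), sum(k_err <= 2))
    expect_identical(nrow(sp$rejected), sum(k_err > 2))
})

test_that("windowed quality filter truncates, length-filters and is idempotent", {
    rule <- filter_rule()
    q35 <- function(n) strrep(intToUtf8(35 + 33L), n)
    clean <- read_set("ok", fixture_dna(1, 253, seed = 60), q35(253))
    qf <- quality_filter(clean, rule)
    expect_identical(qf$kept$seq, clean$seq)
    ## Q10 tail from position 200 truncates below 245 -> discarded
    tail_q <- paste0(q35(199), strrep(intToUtf8(10 + 33L), 54))
    tailed <- read_set("tail", fixture_dna(1, 253, seed = 61), tail_q)
    qf2 <- quality_filter(tailed, rule)
    expect_identical(nrow(qf2$kept), 0L)
    expect_identical(qf2$rejected$reason, "too_short")
    expect_lt(nchar(qf2$rejected$seq), 245)
    ## length boundaries: 244 and 261 discarded; 245, 253, 260 kept
    lens <- c(244, 245, 253, 260, 261)
    batch <- read_set(paste0("L", lens), fixture_dna(5, lens, seed = 62),
                      q35(lens))
    qf3 <- quality_filter(batch, rule)
    expect_identical(qf3$kept$id, c("L245", "L253", "L260"))
    expect_setequal(qf3$rejected$reason, c("too_short", "too_long"))
    ## a single N discards the read
    seqN <- fixture_dna(1, 250, seed = 63)
    substr(seqN, 100, 100) <- "N"
    qfN <- quality_filter(read_set("n1", seqN, q35(250)), rule)
    expect_identical(qfN$rejected$reason, "ambiguous")
    ## idempotence
    mixed <- rbind_reads(clean, tailed, batch)
    once <- quality_filter(mixed, rule)$kept
    twice <- quality_filter(once, rule)$kept
    expect_identical(once, twice)
})

test_that("per-stage accounting conserves reads and a zero-noise batch passes fully", {
    truth <- design_community(community_design(n_lakes = 3,
                                               samples_per_lake = c(2, 2, 2),
                                               frac_ubiquitous = 0.1,
                                               n_otus = 15), seed = 70)
    lay <- read_layout(per_base_error = 0, chimera_rate = 0,
                       lowq_tail_frac = 0)
    sim <- synthesize_reads(truth, lay, depth_per_sample = 60, seed = 70)
    pf <- process_fused_reads(sim$fused$r1, sim$fused$r2, sim$barcodes_fused)
    expect_true(validate_stage_report(pf$report))
    per_sample <- pf$report[!pf$report$sample_id %in% "(all)", ]
    ## no stage loses a read at zero noise
    expect_true(all(per_sample$n_in == per_sample$n_out))
    expect_identical(sum(vapply(pf$ssu, nrow, integer(1))), 60L * 6L)
})
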