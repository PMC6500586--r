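## Study-design constructors and the ground-truth community generator.

#' Environmental-variable design
#'
#' Declares the value range of each environmental variable and which variables
#' are generated as drivers of community composition. Driver variables are
#' tied to a latent between-lake gradient with the given effect size in
#' \[0, 1\] (1 = variable is a deterministic affine map of the gradient,
#' 0 = independent of it); variables absent from `driver_links` are sampled
#' independently per sample, uniformly within their range, so they carry no
#' lake-level signal.
#'
#' Default ranges are those observed across the ten study lakes:
#' pH 8.86-9.68, salinity 0.44-122.39 g/L, TN 0.07-0.88 g/kg, TOC 0.11-2.08 %,
#' sulfate 0.15-5.25 g/L and August monthly-mean surface-water temperature
#' (MMT) 9.95-14.75 degrees C.
#'
#' @param ranges named list of length-2 numeric ranges, one per variable.
#' @param driver_links named numeric vector of effect sizes in \[0, 1\].
#' @param sample_jitter fraction of each range used as within-lake,
#'   per-sample measurement jitter (MMT is a per-lake public record and gets
#'   none).
#' @return An object of class `env_design`.
#' @export
env_design <- function(ranges = list(pH = c(8.86, 9.68),
                                     salinity = c(0.44, 122.39),
                                     TN = c(0.07, 0.88),
                                     TOC = c(0.11, 2.08),
                                     sulfate = c(0.15, 5.25),
                                     MMT = c(9.95, 14.75)),
                       driver_links = c(MMT = 1.0, TN = 0.6),
                       sample_jitter = 0.02) {
    stopifnot(is.list(ranges), length(ranges) >= 1)
    for (v in names(ranges)) {
        r <- ranges[[v]]
        if (length(r) != 2 || !is.numeric(r) || r[1] > r[2])
            stop("range for ", v, " must be numeric c(lo, hi) with lo <= hi")
    }
    if (length(driver_links)) {
        if (is.null(names(driver_links)) || !all(names(driver_links) %in% names(ranges)))
            stop("driver_links must be named after variables in `ranges`")
        if (any(driver_links < 0)) stop("driver effect sizes must be >= 0")
        if (any(driver_links > 1)) stop("driver effect sizes must be <= 1")
    }
    structure(list(ranges = ranges, driver_links = driver_links,
                   sample_jitter = sample_jitter),
              class = "env_design")
}

#' Community design for the synthetic study
#'
#' The design mirrors the field survey the package emulates: 31 sediment
#' samples over 10 saline lakes (2-8 samples per lake), a pool of source taxa
#' partitioned into lake-specific, ubiquitous and intermediate endemism
#' classes, a sulfate-reducer (SRP) subset that carries a dsrB fragment, and
#' long-tailed (log-normal) relative abundances.
#'
#' @param n_lakes number of lakes.
#' @param samples_per_lake integer vector, samples per lake.
#' @param n_otus number of distinct source taxa.
#' @param frac_lake_specific fraction of taxa present in exactly one lake.
#' @param frac_ubiquitous fraction of taxa present in every lake.
#' @param frac_srp fraction of taxa carrying a dsrB segment (fused reads are
#'   emitted only for these).
#' @param abundance_law list with `sdlog` (lake-level log-normal spread),
#'   `sample_sdlog` (within-lake per-sample jitter) and `min_rel` (floor on
#'   the relative abundance of a planted-present taxon, so presence is
#'   recoverable at finite depth).
#' @param gradient_taxa_frac fraction of intermediate taxa whose lake sets are
#'   contiguous windows along the latent environmental gradient (these carry
#'   the community signal that the driver variables track).
#' @param gradient_width kernel width of taxon responses along the gradient.
#' @param seq_len_range range of 16S template lengths (inside the 245-260
#'   quality-filter window).
#' @param dsrb_len length of the dsrB fragment carried by SRP taxa.
#' @param env an [env_design()].
#' @return An object of class `community_design`.
#' @export
community_design <- function(n_lakes = 10,
                             samples_per_lake = c(4, 3, 2, 5, 2, 3, 4, 2, 2, 4),
                             n_otus = 100,
                             frac_lake_specific = 0.675,
                             frac_ubiquitous = 0.02,
                             frac_srp = 0.2,
                             abundance_law = list(sdlog = 1.2,
                                                  sample_sdlog = 0.3,
                                                  min_rel = 0.002),
                             gradient_taxa_frac = 0.8,
                             gradient_width = 0.25,
                             seq_len_range = c(249, 257),
                             dsrb_len = 30,
                             env = env_design()) {
    if (length(samples_per_lake) == 1)
        samples_per_lake <- rep(samples_per_lake, n_lakes)
    if (length(samples_per_lake) != n_lakes)
        stop("samples_per_lake must have one entry per lake")
    if (any(samples_per_lake < 1)) stop("every lake needs at least one sample")
    if (frac_lake_specific < 0 || frac_ubiquitous < 0 || frac_srp < 0 ||
        frac_srp > 1)
        stop("fractions must lie in [0, 1]")
    if (frac_lake_specific + frac_ubiquitous > 1)
        stop("frac_lake_specific + frac_ubiquitous must not exceed 1")
    if (n_otus < 1) stop("n_otus must be positive")
    if (dsrb_len < 1) stop("dsrb_len must be positive")
    stopifnot(inherits(env, "env_design"))
    structure(list(n_lakes = n_lakes,
                   samples_per_lake = as.integer(samples_per_lake),
                   n_otus = as.integer(n_otus),
                   frac_lake_specific = frac_lake_specific,
                   frac_ubiquitous = frac_ubiquitous,
                   frac_srp = frac_srp,
                   abundance_law = abundance_law,
                   gradient_taxa_frac = gradient_taxa_frac,
                   gradient_width = gradient_width,
                   seq_len_range = as.integer(seq_len_range),
                   dsrb_len = as.integer(dsrb_len),
                   env = env),
              class = "community_design")
}

#' Read-layout design for the simulator
#'
#' Describes how raw read pairs are laid out. A bulk 16S pair reads
#' `barcode + fwd_primer + insert-prefix` (forward) and
#' `rev_primer + revcomp(insert-suffix)` (reverse), where the insert is the
#' 16S fragment (mean 253 bp). A fused (epicPCR) pair has the same shape with
#' insert `dsrB(30 bp) + bridging primer + 16S fragment`. `merged_len_fused`
#' is the nominal informative length dsrB + 16S = 283 bp, excluding the
#' bridging primer (which is trimmed away during processing).
#'
#' @param dsrb_len dsrB fragment length (bases).
#' @param bridge_primer IUPAC sequence of the bridging primer separating the
#'   dsrB and 16S fragments inside a fused read.
#' @param barcode_len sample barcode length.
#' @param fwd_primer,rev_primer bulk 16S primer pair (515F / 806R defaults).
#' @param fused_fwd_primer,fused_rev_primer nested fusion primer pair used
#'   for the epicPCR library.
#' @param merged_len_fused nominal merged informative length for fused reads
#'   (must equal `dsrb_len + merged_len_bulk`).
#' @param merged_len_bulk nominal merged length for bulk reads (mean 16S
#'   fragment length).
#' @param read_len insert bases covered by each mate (excluding barcode and
#'   primer).
#' @param per_base_error substitution probability per sequenced base.
#' @param chimera_rate fraction of reads replaced by two-parent single
#'   breakpoint chimeras.
#' @param lowq_tail_frac fraction of read pairs given a low-quality tail at
#'   the merged 3' end (so the windowed quality filter has work to do).
#' @param tail_len range of low-quality tail lengths.
#' @param tail_q,base_q Phred scores of tail and body bases.
#' @return An object of class `read_layout`.
#' @export
read_layout <- function(dsrb_len = 30,
                        bridge_primer = "GWATTACCGCGGCKGCTG",
                        barcode_len = 8,
                        fwd_primer = "GTGCCAGCMGCCGCGGTAA",
                        rev_primer = "GGACTACHVGGGTWTCTAAT",
                        fused_fwd_primer = "CAACATCGTYCAYACMCAGGG",
                        fused_rev_primer = "GGACTACHVGGGTWTCTAAT",
                        merged_len_fused = 283,
                        merged_len_bulk = 253,
                        read_len = 170,
                        per_base_error = 0.005,
                        chimera_rate = 0.01,
                        lowq_tail_frac = 0.02,
                        tail_len = c(20, 40),
                        tail_q = 10,
                        base_q = 35) {
    if (dsrb_len <= 0) stop("dsrb_len must be positive")
    if (per_base_error < 0 || per_base_error >= 0.1)
        stop("per_base_error must lie in [0, 0.1)")
    if (chimera_rate < 0 || chimera_rate > 1)
        stop("chimera_rate must lie in [0, 1]")
    if (merged_len_fused != dsrb_len + merged_len_bulk)
        stop("layout inconsistent: merged_len_fused must equal ",
             "dsrb_len + merged_len_bulk (informative length excludes the ",
             "bridging primer)")
    structure(list(dsrb_len = as.integer(dsrb_len),
                   bridge_primer = bridge_primer,
                   barcode_len = as.integer(barcode_len),
                   fwd_primer = fwd_primer, rev_primer = rev_primer,
                   fused_fwd_primer = fused_fwd_primer,
                   fused_rev_primer = fused_rev_primer,
                   merged_len_fused = as.integer(merged_len_fused),
                   merged_len_bulk = as.integer(merged_len_bulk),
                   read_len = as.integer(read_len),
                   per_base_error = per_base_error,
                   chimera_rate = chimera_rate,
                   lowq_tail_frac = lowq_tail_frac,
                   tail_len = as.integer(tail_len),
                   tail_q = as.integer(tail_q),
                   base_q = as.integer(base_q)),
              class = "read_layout")
}

LAKE_CODES <- c("NMC", "SLC", "DRYC", "YZYC", "BMC",
                "DZC", "DQC", "DJC", "XRC", "DC")

PHYLUM_POOL <- c(Proteobacteria = 0.28, Firmicutes = 0.10, Bacteroidetes = 0.09,
                 Actinobacteria = 0.08, Chloroflexi = 0.07, Acidobacteria = 0.06,
                 Planctomycetes = 0.05, Verrucomicrobia = 0.04,
                 Thaumarchaeota = 0.03, Euryarchaeota = 0.03,
                 Gemmatimonadetes = 0.03, Spirochaetes = 0.02,
                 unclassified = 0.12)

#' Generate the planted ground truth for a synthetic study
#'
#' Draws the full planted truth for one synthetic survey: lake roster and
#' latent environmental gradient, per-taxon endemism class and SRP membership,
#' 16S (and dsrB) template sequences with pairwise identity below 95% (so the
#' 97% clustering threshold separates taxa unambiguously), per-sample true
#' relative abundances, true Shannon indices, and the environmental table.
#'
#' @param design a [community_design()].
#' @param seed integer seed; the same seed reproduces the truth exactly.
#' @return An object of class `epic_truth`: a list with elements `design`,
#'   `lakes` (lake roster with gradient positions), `samples`
#'   (sample-to-lake map), `otus` (per-taxon table: endemism class, SRP flag,
#'   taxonomy, template sequences), `abundance` (samples x taxa true relative
#'   abundances), `presence_lake` (lakes x taxa logical), `true_shannon`, and
#'   `env` (per-sample environmental table).
#' @export
design_community <- function(design = community_design(), seed = 1L) {
    stopifnot(inherits(design, "community_design"))
    set.seed(as.integer(seed))
    n_lakes <- design$n_lakes
    n <- design$n_otus

    lake_id <- if (n_lakes <= length(LAKE_CODES)) LAKE_CODES[seq_len(n_lakes)]
               else sprintf("L%02d", seq_len(n_lakes))
    gradient <- stats::runif(n_lakes)
    lakes <- data.frame(lake_id = lake_id, gradient = gradient,
                        stringsAsFactors = FALSE)

    n_samples <- sum(design$samples_per_lake)
    samples <- data.frame(
        sample_id = sprintf("S%02d", seq_len(n_samples)),
        lake_id = rep(lake_id, design$samples_per_lake),
        stringsAsFactors = FALSE)

    ## endemism classes by rounding the requested fractions
    n_spec <- round(design$frac_lake_specific * n)
    n_ubiq <- round(design$frac_ubiquitous * n)
    if (n_spec + n_ubiq > n) n_spec <- n - n_ubiq
    n_int <- n - n_spec - n_ubiq
    classes <- sample(rep(c("lake-specific", "ubiquitous", "intermediate"),
                          c(n_spec, n_ubiq, n_int)))
    if (n_int > 0 && n_lakes < 3)
        stop("intermediate taxa require at least 3 lakes")

    srp <- rep(FALSE, n)
    srp[sample.int(n, round(design$frac_srp * n))] <- TRUE
    ## keep at least one ubiquitous SRP taxon (cf. the ubiquitous Halomonas
    ## sulfate reducer in saline-lake surveys): every sample then has fused
    ## reads to emit
    ubiq <- which(classes == "ubiquitous")
    if (any(srp) && length(ubiq) && !any(srp[ubiq])) {
        from <- which(srp); from <- from[sample.int(length(from), 1)]
        to <- ubiq[sample.int(length(ubiq), 1)]
        srp[from] <- FALSE
        srp[to] <- TRUE
    }

    ## presence per lake
    lake_order <- order(gradient)
    presence <- matrix(FALSE, n_lakes, n, dimnames = list(lake_id, NULL))
    optimum <- stats::runif(n)
    for (i in seq_len(n)) {
        if (classes[i] == "ubiquitous") {
            presence[, i] <- TRUE
        } else if (classes[i] == "lake-specific") {
            presence[sample.int(n_lakes, 1), i] <- TRUE
        } else {
            k <- sample(2:(n_lakes - 1), 1)
            if (stats::runif(1) < design$gradient_taxa_frac) {
                ## contiguous window along the gradient, centred near optimum
                start <- min(max(1, round(optimum[i] * n_lakes) -
                                    sample.int(k, 1) + 1), n_lakes - k + 1)
                presence[lake_order[start:(start + k - 1)], i] <- TRUE
            } else {
                presence[sample.int(n_lakes, k), i] <- TRUE
            }
        }
    }

    ## template sequences: random, GC ~ 50%, pairwise identity < 95%
    lens <- sample(design$seq_len_range[1]:design$seq_len_range[2], n,
                   replace = TRUE)
    seq16s <- random_dna(n, lens)
    for (iter in seq_len(20)) {
        clash <- FALSE
        for (L in unique(lens)) {
            idx <- which(lens == L)
            if (length(idx) < 2) next
            pairs <- utils::combn(idx, 2)
            d <- cpp_hamming(seq16s[pairs[1, ]], seq16s[pairs[2, ]])
            bad <- which(1 - d / L >= 0.95)
            if (length(bad)) {
                clash <- TRUE
                redo <- unique(pairs[2, bad])
                seq16s[redo] <- random_dna(length(redo), lens[redo])
            }
        }
        if (!clash) break
    }
    dsrb <- ifelse(srp, random_dna(n, design$dsrb_len), NA_character_)

    ## taxonomy: planted phylum and genus labels
    phylum <- sample(names(PHYLUM_POOL), n, replace = TRUE, prob = PHYLUM_POOL)
    genus <- ifelse(phylum == "unclassified", "unclassified",
                    sprintf("%s_genus%02d", substr(phylum, 1, 4),
                            sample.int(12, n, replace = TRUE)))

    otus <- data.frame(otu_id = sprintf("TAX%04d", seq_len(n)),
                       endemism_class = classes, srp = srp,
                       phylum = phylum, genus = genus,
                       length = lens, seq16s = seq16s, dsrb = dsrb,
                       stringsAsFactors = FALSE)

    colnames(presence) <- otus$otu_id

    ## lake-level abundances: log-normal x gradient kernel, then per-sample jitter
    law <- design$abundance_law
    lake_ab <- matrix(0, n_lakes, n, dimnames = list(lake_id, otus$otu_id))
    for (l in seq_len(n_lakes)) {
        present <- presence[l, ]
        base <- stats::rlnorm(sum(present), 0, law$sdlog)
        kern <- exp(-((gradient[l] - optimum[present])^2) /
                        (2 * design$gradient_width^2))
        lake_ab[l, present] <- base * (0.2 + 0.8 * kern)
    }
    abundance <- matrix(0, n_samples, n,
                        dimnames = list(samples$sample_id, otus$otu_id))
    for (s in seq_len(n_samples)) {
        l <- match(samples$lake_id[s], lake_id)
        ab <- lake_ab[l, ] * ifelse(presence[l, ],
                                    stats::rlnorm(n, 0, law$sample_sdlog), 0)
        ab <- ab / sum(ab)
        low <- presence[l, ] & ab < law$min_rel
        ab[low] <- law$min_rel
        abundance[s, ] <- ab / sum(ab)
    }

    true_shannon <- apply(abundance, 1, function(p) {
        p <- p[p > 0]; -sum(p * log(p))
    })

    env <- generate_env(design$env, lakes, samples)

    structure(list(design = design, lakes = lakes, samples = samples,
                   otus = otus, abundance = abundance,
                   presence_lake = presence, true_shannon = true_shannon,
                   env = env),
              class = "epic_truth")
}

## Per-sample environmental table from the lake gradient. Driver variables
## are lake-level maps of the gradient (plus within-lake jitter); non-driver
## variables are drawn independently per sample, so they carry no lake
## signal at all — the planted analog of factors that test non-significant.
generate_env <- function(envd, lakes, samples) {
    n_lakes <- nrow(lakes)
    out <- data.frame(sample_id = samples$sample_id, stringsAsFactors = FALSE)
    for (v in names(envd$ranges)) {
        r <- envd$ranges[[v]]
        eff <- if (v %in% names(envd$driver_links)) envd$driver_links[[v]] else 0
        if (eff > 0) {
            z_lake <- eff * lakes$gradient + (1 - eff) * stats::runif(n_lakes)
            val <- (r[1] + z_lake * (r[2] - r[1]))[
                match(samples$lake_id, lakes$lake_id)]
            if (v != "MMT" && envd$sample_jitter > 0)
                val <- val + stats::rnorm(nrow(samples),
                                          sd = envd$sample_jitter *
                                              (r[2] - r[1]))
        } else {
            val <- r[1] + stats::runif(nrow(samples)) * (r[2] - r[1])
        }
        out[[v]] <- pmin(pmax(val, r[1]), r[2])
    }
    out
}

#' @export
print.epic_truth <- function(x, ...) {
    cat("Planted ground truth:", nrow(x$otus), "taxa,",
        nrow(x$samples), "samples in", nrow(x$lakes), "lakes\n")
    cat("  endemism:", paste(names(table(x$otus$endemism_class)),
                             table(x$otus$endemism_class),
                             collapse = ", ", sep = " = "), "\n")
    cat("  SRP taxa:", sum(x$otus$srp), "\n")
    invisible(x)
}
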