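## Alpha diversity (richness, Shannon, Chao1, rarefaction curves) and beta
## diversity (binary Jaccard, weighted UniFrac, PCoA).

## Accept either a counts matrix (samples x OTUs) or an otu_table.
counts_of <- function(x) {
    if (inherits(x, "otu_table")) return(x$counts)
    if (is.matrix(x)) return(x)
    if (is.numeric(x)) return(matrix(x, 1, dimnames = list("sample",
                                                           names(x))))
    stop("expected an otu_table, a counts matrix or a count vector")
}

#' Shannon diversity index
#'
#' H = -sum p_i ln p_i over nonzero relative abundances, natural logarithm.
#'
#' @param x count vector, samples x OTUs matrix, or `otu_table`.
#' @return Named numeric vector of H per sample.
#' @export
shannon_index <- function(x) {
    m <- counts_of(x)
    if (any(m < 0)) stop("counts must be non-negative")
    if (any(rowSums(m) == 0)) stop("sample with all-zero counts")
    vegan::diversity(m, index = "shannon")
}

#' Chao1 richness estimator (bias-corrected)
#'
#' S_chao1 = S_obs + F1 (F1 - 1) / (2 (F2 + 1)), with F1/F2 the singleton and
#' doubleton counts. The classic form S_obs + F1^2 / (2 F2) is available via
#' `bias_corrected = FALSE` (undefined when F2 = 0).
#'
#' @param x count vector, matrix or `otu_table` (integer counts).
#' @param bias_corrected use the bias-corrected form (default TRUE).
#' @return Named numeric vector of Chao1 estimates per sample.
#' @export
chao1_index <- function(x, bias_corrected = TRUE) {
    m <- counts_of(x)
    if (any(m != round(m)))
        stop("Chao1 requires integer counts")
    apply(m, 1, function(v) {
        s_obs <- sum(v > 0)
        f1 <- sum(v == 1); f2 <- sum(v == 2)
        if (bias_corrected) s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
        else if (f2 > 0) s_obs + f1^2 / (2 * f2)
        else { warning("F2 = 0: classic Chao1 undefined, returning NA"); NA_real_ }
    })
}

#' Observed richness, Shannon and Chao1 per sample
#'
#' @param x counts matrix or `otu_table`.
#' @return Data frame with `sample_id`, `richness`, `shannon`, `chao1`.
#' @export
alpha_diversity <- function(x) {
    m <- counts_of(x)
    data.frame(sample_id = rownames(m),
               richness = rowSums(m > 0),
               shannon = shannon_index(m),
               chao1 = chao1_index(m),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Monte-Carlo rarefaction curve
#'
#' Mean observed richness over `reps` without-replacement subsamples at each
#' depth. Matches the analytic hypergeometric expectation
#' E\[S(d)\] = sum_i (1 - C(N - N_i, d) / C(N, d)) within Monte-Carlo error.
#'
#' @param counts count vector for one sample.
#' @param depths subsampling depths (each <= total reads).
#' @param reps subsamples per depth (default 10).
#' @param seed integer seed.
#' @return Data frame with `depth` and `mean_richness`.
#' @export
rarefaction_curve <- function(counts, depths, reps = 10, seed = 1L) {
    counts <- as.integer(counts)
    total <- sum(counts)
    if (any(depths > total)) stop("depth exceeds sample total")
    if (any(depths < 1)) stop("depths must be positive")
    set.seed(as.integer(seed))
    mean_rich <- vapply(depths, function(d) {
        mean(vapply(seq_len(reps), function(r) {
            sum(draw_without_replacement(counts, d) > 0)
        }, numeric(1)))
    }, numeric(1))
    data.frame(depth = depths, mean_richness = mean_rich)
}

#' Binary Jaccard distance matrix
#'
#' d(A, B) = 1 - |A intersect B| / |A union B| on presence/absence profiles.
#' A quantitative (Ruzicka) variant is available for sensitivity analysis.
#'
#' @param x counts matrix (samples x OTUs) or `otu_table`.
#' @param mode `"binary"` (set-theoretic, default) or `"quantitative"`.
#' @return Symmetric distance matrix with sample labels.
#' @export
jaccard_matrix <- function(x, mode = c("binary", "quantitative")) {
    mode <- match.arg(mode)
    m <- counts_of(x)
    if (any(rowSums(m) == 0))
        stop("sample with zero OTUs: ",
             paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
    d <- vegan::vegdist(m, method = "jaccard", binary = mode == "binary")
    as.matrix(d)
}

#' Weighted UniFrac distance matrix
#'
#' raw d(A, B) = sum_b l_b |p_A(b) - p_B(b)| over branches b with length l_b,
#' where p_X(b) is the fraction of sample X's reads descending from b. The
#' normalized form divides by sum_b l_b (p_A(b) + p_B(b)) and lies in
#' \[0, 1\].
#'
#' @param x counts matrix (samples x OTUs) or `otu_table`; column names must
#'   appear among the tree's tip labels for every OTU with nonzero counts.
#' @param tree a rooted `phylo` tree with branch lengths (leaves labelled by
#'   OTU id); extra tips are allowed.
#' @param normalized return the normalized form (default TRUE).
#' @return Symmetric distance matrix with sample labels.
#' @export
weighted_unifrac <- function(x, tree, normalized = TRUE) {
    m <- counts_of(x)
    stopifnot(inherits(tree, "phylo"))
    if (is.null(tree$edge.length)) stop("tree must have branch lengths")
    if (any(tree$edge.length < 0)) stop("branch lengths must be >= 0")
    nz <- colnames(m)[colSums(m) > 0]
    missing <- setdiff(nz, tree$tip.label)
    if (length(missing))
        stop("OTU(s) absent from the tree: ",
             paste(missing, collapse = ", "))
    rel <- m / rowSums(m)
    ntip <- length(tree$tip.label)
    nnode <- ntip + tree$Nnode
    ## tip fractions per sample, then postorder accumulation to all nodes
    frac <- matrix(0, nnode, nrow(m))
    idx <- match(colnames(m), tree$tip.label)
    ok <- !is.na(idx)
    frac[idx[ok], ] <- t(rel[, ok, drop = FALSE])
    edge <- ape::reorder.phylo(tree, "postorder")$edge
    for (e in seq_len(nrow(edge)))
        frac[edge[e, 1], ] <- frac[edge[e, 1], ] + frac[edge[e, 2], ]
    ## per-branch descendant fractions: child node of each edge
    pe <- match(paste(edge[, 1], edge[, 2]),
                paste(tree$edge[, 1], tree$edge[, 2]))
    bl <- tree$edge.length[pe]
    E <- frac[edge[, 2], , drop = FALSE]          # branches x samples
    n <- nrow(m)
    d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
        raw <- sum(bl * abs(E[, a] - E[, b]))
        if (normalized) {
            den <- sum(bl * (E[, a] + E[, b]))
            raw <- if (den > 0) raw / den else 0
        }
        d[a, b] <- d[b, a] <- raw
    }
    d
}

#' Principal coordinates analysis (PCoA)
#'
#' Gower double-centering of -D^2/2 followed by eigendecomposition.
#' Coordinates are eigenvector times sqrt(eigenvalue) for positive
#' eigenvalues; negative eigenvalues are reported but excluded from the
#' percent-variance denominator. A Cailliez additive correction is available
#' behind a flag.
#'
#' @param d symmetric distance matrix with sample labels.
#' @param correction `"none"` (default) or `"cailliez"`.
#' @return List of class `epic_pcoa` with `points` (samples x axes),
#'   `eigenvalues` (all, decreasing), and `percent` (variance explained per
#'   positive axis).
#' @export
pcoa_ordination <- function(d, correction = c("none", "cailliez")) {
    correction <- match.arg(correction)
    check_distance_matrix(d)
    n <- nrow(d)
    res <- suppressWarnings(
        stats::cmdscale(stats::as.dist(d), k = n - 1, eig = TRUE,
                        add = correction == "cailliez"))
    eig <- res$eig
    pos <- eig > sqrt(.Machine$double.eps) * max(abs(eig))
    k2 <- min(sum(pos), ncol(res$points))
    pts <- res$points[, seq_len(k2), drop = FALSE]
    colnames(pts) <- sprintf("Axis%d", seq_len(ncol(pts)))
    structure(list(points = pts,
                   eigenvalues = eig,
                   percent = 100 * eig[pos] / sum(eig[pos])),
              class = "epic_pcoa")
}

#' @export
print.epic_pcoa <- function(x, ...) {
    cat("PCoA ordination:", nrow(x$points), "samples,",
        ncol(x$points), "axes\n")
    k <- min(3, length(x$percent))
    cat("  variance explained:",
        paste(sprintf("%s %.1f%%", colnames(x$points)[seq_len(k)],
                      x$percent[seq_len(k)]), collapse = ", "), "\n")
    invisible(x)
}
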