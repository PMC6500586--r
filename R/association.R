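## Environment-community association: standardization, Euclidean environment
## distances, permutation Mantel tests, and alpha-diversity correlations.

env_matrix <- function(env, variables = NULL) {
    if (is.data.frame(env)) {
        ids <- if ("sample_id" %in% names(env)) env$sample_id
               else rownames(env)
        m <- as.matrix(env[, setdiff(names(env), "sample_id"), drop = FALSE])
        rownames(m) <- ids
    } else m <- as.matrix(env)
    if (!is.null(variables)) {
        bad <- setdiff(variables, colnames(m))
        if (length(bad)) stop("unknown variable(s): ",
                              paste(bad, collapse = ", "))
        m <- m[, variables, drop = FALSE]
    }
    if (!ncol(m)) stop("no environmental variables selected")
    if (anyNA(m)) stop("environmental table contains missing values")
    m
}

#' Z-score standardization of environmental variables
#'
#' Per-variable centering and scaling to unit sample standard deviation
#' (n - 1 convention). Idempotent up to floating point.
#'
#' @param env data frame (with `sample_id`) or numeric matrix, samples x
#'   variables.
#' @return Object of the same shape with standardized values.
#' @export
standardize_env <- function(env) {
    m <- env_matrix(env)
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0))
        stop("constant variable(s): ",
             paste(colnames(m)[sds == 0], collapse = ", "))
    z <- scale(m)
    attr(z, "scaled:center") <- NULL
    attr(z, "scaled:scale") <- NULL
    if (is.data.frame(env)) {
        out <- env
        out[, colnames(z)] <- z
        out
    } else z
}

#' Euclidean distance over selected environmental variables
#'
#' Pairwise L2 distance over the chosen columns (a single column for the
#' per-factor Mantel rows). Standardize first with [standardize_env()] when
#' variables are on different scales.
#'
#' @param env data frame or matrix, samples x variables.
#' @param variables variable subset (default all).
#' @return Symmetric distance matrix with sample labels.
#' @export
euclidean_matrix <- function(env, variables = NULL) {
    m <- env_matrix(env, variables)
    as.matrix(stats::dist(m, method = "euclidean"))
}

## All permutations of 1..n (n small), one per row.
all_permutations <- function(n) {
    if (n == 1) return(matrix(1L, 1, 1))
    sub <- all_permutations(n - 1)
    out <- matrix(0L, n * nrow(sub), n)
    r <- 0
    for (k in seq_len(n)) {
        rows <- r + seq_len(nrow(sub))
        out[rows, 1] <- k
        rest <- seq_len(n)[-k]
        out[rows, -1] <- matrix(rest[sub], nrow(sub))
        r <- r + nrow(sub)
    }
    out
}

#' Permutation Mantel test
#'
#' r_M is the Pearson correlation of the n(n-1)/2 upper-triangle entries of
#' the two distance matrices. The p-value permutes rows and columns of `dy`
#' jointly: with random permutations it is
#' (1 + #\{r_perm >= r_obs\}) / (n_perm + 1) (one-tailed, positive
#' association, by default); with `exhaustive = TRUE` all n! permutations are
#' enumerated (identity included) and p = #\{r_perm >= r_obs\} / n!.
#'
#' @param dx,dy symmetric distance matrices over the same samples (matching
#'   labels; `dy` is reordered to `dx`'s labels when both are labelled).
#' @param n_perm number of random permutations (default 999).
#' @param seed integer seed for the permutation draw.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @param exhaustive enumerate all permutations (requires n <= 8).
#' @return Object of class `epic_mantel`: list with `statistic` (r_M),
#'   `p.value`, `n_perm`, `alternative`.
#' @export
mantel_test <- function(dx, dy, n_perm = 999, seed = NULL,
                        alternative = c("greater", "less", "two.sided"),
                        exhaustive = FALSE) {
    alternative <- match.arg(alternative)
    check_distance_matrix(dx, "dx"); check_distance_matrix(dy, "dy")
    n <- nrow(dx)
    if (n < 4) stop("Mantel test needs at least 4 samples")
    if (nrow(dy) != n) stop("dx and dy must have the same dimension")
    if (!is.null(rownames(dx)) && !is.null(rownames(dy))) {
        if (!setequal(rownames(dx), rownames(dy)))
            stop("dx and dy sample labels do not match")
        dy <- dy[rownames(dx), rownames(dx)]
    }
    ut <- upper.tri(dx)
    xv <- dx[ut]; yv <- dy[ut]
    if (stats::sd(xv) == 0 || stats::sd(yv) == 0)
        stop("degenerate distance matrix: zero variance among distances")
    r_obs <- stats::cor(xv, yv)
    ii <- row(dx)[ut]; jj <- col(dx)[ut]
    if (exhaustive) {
        if (n > 8) stop("exhaustive enumeration limited to n <= 8")
        P <- all_permutations(n)
    } else {
        if (!is.null(seed)) set.seed(as.integer(seed))
        P <- t(vapply(seq_len(n_perm), function(k) sample.int(n),
                      integer(n)))
    }
    ## permuted upper triangles, one permutation per row
    Y <- matrix(dy[cbind(as.vector(P[, ii]), as.vector(P[, jj]))],
                nrow = nrow(P))
    r_perm <- suppressWarnings(as.vector(stats::cor(t(Y), xv)))
    eps <- 1e-12
    exceed <- switch(alternative,
                     greater = r_perm >= r_obs - eps,
                     less = r_perm <= r_obs + eps,
                     two.sided = abs(r_perm) >= abs(r_obs) - eps)
    p <- if (exhaustive) sum(exceed) / nrow(P)
         else (1 + sum(exceed)) / (n_perm + 1)
    structure(list(statistic = r_obs, p.value = p,
                   n_perm = nrow(P), alternative = alternative,
                   exhaustive = exhaustive),
              class = "epic_mantel")
}

#' @export
print.epic_mantel <- function(x, ...) {
    cat(sprintf("Mantel test: r_M = %.4f, p = %.4g (%s, %s%d permutations)\n",
                x$statistic, x$p.value, x$alternative,
                if (x$exhaustive) "exhaustive " else "", x$n_perm))
    invisible(x)
}

#' Per-factor Mantel screen of environmental variables
#'
#' Standardizes the environmental table, builds a single-variable Euclidean
#' distance matrix per factor (plus an optional all-variable row) and runs a
#' Mantel test of each against the community distance matrix — the layout of
#' the study's per-factor association table.
#'
#' @param dcom community distance matrix (e.g. binary Jaccard).
#' @param env environmental table (data frame with `sample_id`).
#' @param variables factors to test (default: all).
#' @param include_all also test the combined all-variable distance.
#' @param n_perm,seed,alternative passed to [mantel_test()].
#' @return Data frame with `factor`, `r_M`, `p`.
#' @export
mantel_env_screen <- function(dcom, env, variables = NULL,
                              include_all = TRUE, n_perm = 999, seed = NULL,
                              alternative = "greater") {
    z <- standardize_env(env)
    zm <- env_matrix(z)
    zm <- zm[rownames(dcom), , drop = FALSE]
    variables <- variables %||% colnames(zm)
    rows <- lapply(variables, function(v) {
        mt <- mantel_test(dcom, euclidean_matrix(zm, v), n_perm = n_perm,
                          seed = seed, alternative = alternative)
        data.frame(factor = v, r_M = mt$statistic, p = mt$p.value,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (include_all) {
        mt <- mantel_test(dcom, euclidean_matrix(zm), n_perm = n_perm,
                          seed = seed, alternative = alternative)
        out <- rbind(out, data.frame(factor = "(all)", r_M = mt$statistic,
                                     p = mt$p.value, stringsAsFactors = FALSE))
    }
    rownames(out) <- NULL
    out
}

#' Correlation between two alpha-diversity series
#'
#' Pearson, Kendall or Spearman correlation between per-sample Shannon
#' indices of the whole community and the SRP sub-community (or any two
#' aligned series), with the p-value of the corresponding test.
#'
#' @param h_community,h_srp numeric vectors of equal length (>= 3).
#' @param method `"pearson"`, `"kendall"` or `"spearman"`.
#' @return List with `estimate`, `p.value`, `method`.
#' @export
alpha_correlation <- function(h_community, h_srp,
                              method = c("pearson", "kendall", "spearman")) {
    method <- match.arg(method)
    if (length(h_community) != length(h_srp))
        stop("series must have equal length")
    if (length(h_community) < 3) stop("need at least 3 samples")
    if (stats::var(h_community) == 0 || stats::var(h_srp) == 0)
        stop("zero-variance input")
    ct <- suppressWarnings(stats::cor.test(h_community, h_srp,
                                           method = method))
    list(estimate = unname(ct$estimate), p.value = ct$p.value,
         method = method)
}
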