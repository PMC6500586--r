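## Independent oracles (plain R, no package kernels) and fixture builders.

## Quadratic Needleman-Wunsch with match +1 / mismatch -1 / linear gap -2,
## end gaps penalized; identity = matches / alignment columns of the
## optimal-score alignment (ties resolved diagonal > up > left, matching the
## declared convention).
oracle_identity <- function(a, b) {
    A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
    n <- length(A); m <- length(B)
    S <- matrix(0, n + 1, m + 1)
    D <- matrix(0L, n + 1, m + 1)  # 1 diag, 2 up, 3 left
    S[1, ] <- -2 * (0:m); S[, 1] <- -2 * (0:n)
    D[1, -1] <- 3L; D[-1, 1] <- 2L
    for (i in seq_len(n)) for (j in seq_len(m)) {
        sc <- c(S[i, j] + if (A[i] == B[j]) 1 else -1,
                S[i, j + 1] - 2, S[i + 1, j] - 2)
        k <- which.max(sc)
        S[i + 1, j + 1] <- sc[k]; D[i + 1, j + 1] <- k
    }
    i <- n + 1; j <- m + 1; matches <- 0; cols <- 0
    while (i > 1 || j > 1) {
        d <- D[i, j]
        if (d == 1L) {
            if (A[i - 1] == B[j - 1]) matches <- matches + 1
            i <- i - 1; j <- j - 1
        } else if (d == 2L) i <- i - 1 else j <- j - 1
        cols <- cols + 1
    }
    matches / cols
}

## Greedy clustering oracle: same declared scan, identity via oracle_identity
## (gapless shortcut for equal lengths, as declared).
oracle_greedy <- function(seqs, thr = 0.97) {
    otu <- integer(length(seqs))
    centroids <- integer(0)
    for (i in seq_along(seqs)) {
        hit <- 0L
        for (ci in seq_along(centroids)) {
            a <- seqs[i]; b <- seqs[centroids[ci]]
            id <- if (nchar(a) == nchar(b))
                mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
            else oracle_identity(a, b)
            if (id >= thr - 1e-12) { hit <- ci; break }
        }
        if (hit == 0L) { centroids <- c(centroids, i); otu[i] <- length(centroids) }
        else otu[i] <- hit
    }
    otu
}

## Hamming distance between two equal-length strings.
oracle_hamming <- function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

## Guarded two-parent chimera rule, sequential over abundance-sorted uniques.
oracle_chimera <- function(seqs, abund, skew = 2, ident = 0.99,
                           min_seg = 30) {
    n <- length(seqs)
    flagged <- logical(n)
    seg_ok <- function(u, p, from_left) {
        ## returns logical vector over segment length 1..min(L, Lp)
        U <- strsplit(u, "")[[1]]; P <- strsplit(p, "")[[1]]
        m <- min(length(U), length(P))
        if (!from_left) { U <- rev(U); P <- rev(P) }
        mm <- cumsum(U[seq_len(m)] != P[seq_len(m)])
        seq_len(m) >= min_seg & mm <= (1 - ident) * seq_len(m) + 1e-9
    }
    for (k in seq_len(n)) {
        L <- nchar(seqs[k])
        if (L < 2 * min_seg) next
        parents <- which(!flagged & abund >= skew * abund[k] &
                             seq_len(n) != k)
        if (length(parents) < 2) next
        explained <- FALSE
        for (p in parents) {
            m <- min(L, nchar(seqs[p]))
            if (m < ident * L) next
            U <- strsplit(seqs[k], "")[[1]]; P <- strsplit(seqs[p], "")[[1]]
            mm_pre <- sum(U[seq_len(m)] != P[seq_len(m)])
            mm_suf <- sum(rev(U)[seq_len(m)] != rev(P)[seq_len(m)])
            if ((m - min(mm_pre, mm_suf)) / L >= ident) { explained <- TRUE; break }
        }
        if (explained) next
        flag <- FALSE
        left <- lapply(parents, function(p) seg_ok(seqs[k], seqs[p], TRUE))
        right <- lapply(parents, function(p) seg_ok(seqs[k], seqs[p], FALSE))
        for (s in min_seg:(L - min_seg)) {
            lp <- parents[vapply(left, function(v) length(v) >= s && v[s],
                                 logical(1))]
            seg <- L - s
            rp <- parents[vapply(right, function(v) length(v) >= seg && v[seg],
                                 logical(1))]
            if (length(lp) && length(rp) && length(union(lp, rp)) > 1) {
                flag <- TRUE; break
            }
        }
        flagged[k] <- flag
    }
    flagged
}

## FLASH-style merge oracle: scan every overlap, min mismatch ratio, ties to
## the longer overlap.
oracle_merge <- function(fseq, fqual, rseq_rc, rqual_rev, min_overlap = 30,
                         max_frac = 0.25) {
    F <- strsplit(fseq, "")[[1]]; R <- strsplit(rseq_rc, "")[[1]]
    FQ <- utf8ToInt(fqual) - 33L; RQ <- utf8ToInt(rqual_rev) - 33L
    L1 <- length(F); L2 <- length(R)
    best <- NULL
    for (v in min_overlap:min(L1, L2)) {
        mm <- sum(F[(L1 - v + 1):L1] != R[1:v])
        ratio <- mm / v
        if (is.null(best) || ratio < best$ratio ||
            (ratio == best$ratio && v > best$v))
            best <- list(v = v, ratio = ratio)
    }
    if (is.null(best) || best$ratio > max_frac) return(NULL)
    v <- best$v
    rtail <- if (L2 > v) R[(v + 1):L2] else character(0)
    qtail <- if (L2 > v) RQ[(v + 1):L2] else integer(0)
    s <- c(F[seq_len(L1 - v)], character(v), rtail)
    q <- c(FQ[seq_len(L1 - v)], integer(v), qtail)
    for (i in seq_len(v)) {
        cf <- F[L1 - v + i]; cr <- R[i]
        qf <- FQ[L1 - v + i]; qr <- RQ[i]
        s[L1 - v + i] <- if (cf == cr) cf else if (qr > qf) cr else cf
        q[L1 - v + i] <- max(qf, qr)
    }
    list(seq = paste(s, collapse = ""),
         qual = intToUtf8(q + 33L))
}

## All permutations of 1..n as a matrix (rowwise), recursive.
oracle_perms <- function(n) {
    if (n == 1) return(matrix(1L, 1, 1))
    sub <- oracle_perms(n - 1)
    do.call(rbind, lapply(seq_len(n), function(k) {
        rest <- seq_len(n)[-k]
        cbind(k, matrix(rest[sub], nrow(sub)))
    }))
}

## Exhaustive Mantel p-value oracle.
oracle_mantel_exact <- function(dx, dy) {
    n <- nrow(dx)
    ut <- upper.tri(dx)
    r_obs <- cor(dx[ut], dy[ut])
    P <- oracle_perms(n)
    r_perm <- apply(P, 1, function(p) cor(dx[ut], dy[p, p][ut]))
    mean(r_perm >= r_obs - 1e-12)
}

## Procrustes RMS after optimal translation + rotation/reflection.
procrustes_rms <- function(target, points) {
    X <- scale(target, scale = FALSE)
    Y <- scale(points, scale = FALSE)
    sv <- svd(crossprod(Y, X))
    Q <- sv$u %*% t(sv$v)
    sqrt(mean((Y %*% Q - X)^2))
}

## Deterministic random DNA for fixtures.
fixture_dna <- function(n, len, seed = 1) {
    set.seed(seed)
    vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"),
                     if (length(len) > 1) len[i] else len,
                     replace = TRUE), collapse = ""), character(1))
}

## Mutate k positions of a sequence (substitutions at distinct sites).
mutate_seq <- function(s, k, seed = 1) {
    set.seed(seed)
    ch <- strsplit(s, "")[[1]]
    pos <- sample(length(ch), k)
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    paste(ch, collapse = "")
}

## Build a perfect raw read pair for a given insert (exact barcode/primers,
## constant quality), overlapping by 2 * core - nchar(insert).
make_pair <- function(insert, barcode, fwdp, revp, core = 170, q = 35,
                      id = "read1", r2_qual = NULL) {
    L <- nchar(insert)
    stopifnot(core < L, 2 * core - L >= 30)
    r1 <- paste0(barcode, fwdp, substr(insert, 1, core))
    rc <- function(x) as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(x)))
    r2 <- paste0(revp, rc(substr(insert, L - core + 1, L)))
    qs <- function(n) strrep(intToUtf8(q + 33L), n)
    list(r1 = read_set(id, r1, qs(nchar(r1))),
         r2 = read_set(paste0(id, "/2"), r2,
                       r2_qual %||% qs(nchar(r2))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rbind_reads <- function(...) {
    out <- do.call(rbind, list(...))
    rownames(out) <- NULL
    class(out) <- c("read_set", "data.frame")
    out
}
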