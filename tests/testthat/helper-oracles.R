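# Independent oracles used to validate the package implementations on small
# instances. These deliberately avoid the code paths they check.

# Affine-gap global alignment score by dynamic programming (Gotoh). Gap run
# of length L costs open + L * ext, matching the package's convention.
dp_align_score <- function(a, b, match = 2, mismatch = -1, open = 4, ext = 1) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(ca); m <- length(cb)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)   # last move: diagonal
  X <- matrix(NEG, n + 1L, m + 1L)   # last move: gap in b (consume a)
  Y <- matrix(NEG, n + 1L, m + 1L)   # last move: gap in a (consume b)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1L, 1L] <- -(open + i * ext)
  for (j in seq_len(m)) Y[1L, j + 1L] <- -(open + j * ext)
  s <- function(x, y) if (x == y) match else mismatch
  for (i in seq_len(n)) for (j in seq_len(m)) {
    sc <- s(ca[i], cb[j])
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + sc
    X[i + 1, j + 1] <- max(M[i, j + 1] - (open + ext), X[i, j + 1] - ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - (open + ext), Y[i + 1, j] - ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Exhaustive enumeration of all gapped alignments (tiny strings only),
# scoring gap runs as open + L * ext.
enum_align_score <- function(a, b, match = 2, mismatch = -1, open = 4,
                             ext = 1) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  rec <- function(i, j, last) {
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      sc <- if (ca[i] == cb[j]) match else mismatch
      best <- max(best, sc + rec(i + 1L, j + 1L, "d"))
    }
    if (i <= length(ca)) {
      cost <- ext + if (last != "x") open else 0
      best <- max(best, -cost + rec(i + 1L, j, "x"))
    }
    if (j <= length(cb)) {
      cost <- ext + if (last != "y") open else 0
      best <- max(best, -cost + rec(i, j + 1L, "y"))
    }
    best
  }
  rec(1L, 1L, "d")
}

# Position-by-position IUPAC motif scan (no regex).
iupac_allowed <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T", "N"))

brute_scan <- function(seq, consensus) {
  sc <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  pc <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  L <- length(pc)
  out <- integer(0)
  if (length(sc) < L) return(out)
  for (s in seq_len(length(sc) - L + 1L)) {
    ok <- TRUE
    for (j in seq_len(L)) {
      if (!(sc[s + j - 1L] %in% iupac_allowed[[pc[j]]])) { ok <- FALSE; break }
    }
    if (ok) out <- c(out, s - 1L)
  }
  out
}

# Literal per-position reading of the basal+extension rule: position x is in
# gene g's extended domain iff it is in the basal domain, or lies between the
# basal domain and the nearest same-side neighbour basal boundary, within
# max_ext.
great_oracle_member <- function(x, g, genes, basal_up = 5000,
                                basal_down = 1000, max_ext = 1e6) {
  basal <- function(k) {
    up <- if (genes$strand[k] == "+") basal_up else basal_down
    dn <- if (genes$strand[k] == "+") basal_down else basal_up
    c(max(0, genes$tss[k] - up), genes$tss[k] + dn)
  }
  b <- basal(g)
  if (x >= b[1] && x < b[2]) return(TRUE)
  same <- which(genes$contig == genes$contig[g])
  if (x < b[1]) {
    if (x < b[1] - max_ext) return(FALSE)
    left <- same[genes$tss[same] < genes$tss[g] |
                   (genes$tss[same] == genes$tss[g] & same < g)]
    for (k in left) if (x < min(basal(k)[2], b[1])) return(FALSE)
    return(TRUE)
  }
  if (x >= b[2] + max_ext) return(FALSE)
  right <- same[genes$tss[same] > genes$tss[g] |
                  (genes$tss[same] == genes$tss[g] & same > g)]
  for (k in right) if (x >= max(basal(k)[1], b[2])) return(FALSE)
  TRUE
}

# One-way ANOVA F from raw sums of squares.
anova_oracle_F <- function(groups) {
  y <- unlist(groups)
  gmeans <- vapply(groups, mean, 0)
  grand <- mean(y)
  ssb <- sum(vapply(seq_along(groups), function(i)
    length(groups[[i]]) * (gmeans[i] - grand)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- length(groups) - 1
  df2 <- length(y) - length(groups)
  (ssb / df1) / (ssw / df2)
}

# Exact 99% binomial interval for a count at probability p.
binom_ci99 <- function(p, n) {
  c(qbinom(0.005, n, p), qbinom(0.995, n, p))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
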