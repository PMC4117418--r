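# Independent brute-force oracles and fixture builders. Everything here is
# written as plainly as possible (double loops, full enumeration) and never
# shares code with the implementation it checks.

## -- mixture model oracles ---------------------------------------------------

# Eq-style weighted KDE: f_jk(u) = 1/(n lambda_j h) sum_i p_ij K((u - x_ik)/h)
oracle_kde <- function(u, xk, weights_j, lambda_j, h) {
  n <- length(xk)
  total <- 0
  for (i in seq_len(n))
    total <- total + weights_j[i] * dnorm((u - xk[i]) / h)
  total / (n * lambda_j * h)
}

# posterior p_ij proportional to lambda_j prod_k f_jk(x_ik)
oracle_estep <- function(x, lambda, train_x, train_w, h) {
  n <- nrow(x); r <- ncol(x); m <- length(lambda)
  p <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      prod_f <- lambda[j]
      for (k in seq_len(r))
        prod_f <- prod_f * oracle_kde(x[i, k], train_x[, k], train_w[, j],
                                      lambda[j], h)
      p[i, j] <- prod_f
    }
    p[i, ] <- p[i, ] / sum(p[i, ])
  }
  p
}

oracle_mstep <- function(posteriors) {
  m <- ncol(posteriors); n <- nrow(posteriors)
  lambda <- numeric(m)
  for (j in seq_len(m)) {
    s <- 0
    for (i in seq_len(n)) s <- s + posteriors[i, j]
    lambda[j] <- s / n
  }
  lambda
}

## -- silhouette oracle (O(n^2) pairwise distances) ---------------------------

oracle_silhouette <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- function(i, j) sqrt(sum((x[i, ] - x[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(vapply(own, function(j) d(i, j), numeric(1)))
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      other <- which(labels == cl)
      b <- min(b, mean(vapply(other, function(j) d(i, j), numeric(1))))
    }
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  s
}

## -- permutation-test oracles ------------------------------------------------

# all permutations of 1..n (n <= 8)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 0L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (r in seq_len(nrow(sub))) {
      row <- row + 1L
      out[row, ] <- c(k, rest[sub[r, ]])
    }
  }
  out
}

# quadratic-form statistic computed independently (MASS::ginv)
oracle_assoc_stat <- function(x, y) {
  classes <- sort(unique(y))
  n <- length(x)
  Tj <- vapply(classes, function(c) sum(x[y == c]), numeric(1))
  nj <- vapply(classes, function(c) sum(y == c), numeric(1))
  mu <- mean(x) * nj
  Vg <- mean((x - mean(x))^2)
  Sigma <- Vg * (n / (n - 1)) *
    (diag(nj, nrow = length(nj)) - outer(nj, nj) / n)
  d <- Tj - mu
  drop(t(d) %*% MASS::ginv(Sigma) %*% d)
}

# exact permutation p-value of the quadratic-form statistic
oracle_perm_pvalue <- function(x, y) {
  obs <- oracle_assoc_stat(x, y)
  perms <- all_perms(length(x))
  stats <- apply(perms, 1L, function(p) oracle_assoc_stat(x[p], y))
  mean(stats >= obs - 1e-9)
}

# exhaustive best binary split: score every cut by the quadratic-form
# two-sample statistic, building the full covariance and MASS::ginv per cut
oracle_best_split <- function(x, y, minbucket = 1L) {
  classes <- sort(unique(y))
  n <- length(x)
  nj <- vapply(classes, function(c) sum(y == c), numeric(1))
  cands <- sort(unique(x))
  best <- NULL; best_score <- -Inf
  for (v in cands) {
    nl <- sum(x <= v)
    if (nl < minbucket || n - nl < minbucket) next
    Tj <- vapply(classes, function(c) sum(x <= v & y == c), numeric(1))
    mu <- nl * nj / n
    Vg <- (nl / n) * (1 - nl / n)
    Sigma <- Vg * (n / (n - 1)) *
      (diag(nj, nrow = length(nj)) - outer(nj, nj) / n)
    d <- Tj - mu
    score <- drop(t(d) %*% MASS::ginv(Sigma) %*% d)
    if (score > best_score + 1e-9) { best_score <- score; best <- v }
  }
  list(split = best, score = best_score)
}

## -- adjusted Rand index -----------------------------------------------------

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- choose2(as.vector(tab))
  sum_a <- choose2(rowSums(tab))
  sum_b <- choose2(colSums(tab))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

## -- fixture builders --------------------------------------------------------

# two well-separated blobs in `dims` dimensions
two_blobs <- function(n_per = 20, sep = 10, sd = 1, dims = 2, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * dims, 0, sd), n_per),
             matrix(rnorm(n_per * dims, sep, sd), n_per))
  colnames(x) <- paste0("M", seq_len(dims))
  list(table = expr_table(x, transformed = TRUE),
       labels = rep(1:2, each = n_per))
}

# minimal FCS 3.0 writer (float or double, little or big endian) used to
# round-trip the reader; supports $PnS names and $PnN short names
write_fcs_fixture <- function(path, data, short_names = colnames(data),
                              stain_names = NULL, datatype = "F",
                              endian = "little", version = "FCS3.0") {
  n_par <- ncol(data); n_tot <- nrow(data)
  size <- if (datatype == "F") 4L else 8L
  byteord <- if (endian == "little") "1,2,3,4" else "4,3,2,1"
  kw <- c("$DATATYPE", datatype, "$MODE", "L", "$BYTEORD", byteord,
          "$PAR", n_par, "$TOT", n_tot, "$NEXTDATA", 0)
  for (i in seq_len(n_par)) {
    kw <- c(kw, sprintf("$P%dB", i), size * 8L,
            sprintf("$P%dN", i), short_names[i],
            sprintf("$P%dE", i), "0,0",
            sprintf("$P%dR", i), 262144)
    if (!is.null(stain_names) && !is.na(stain_names[i]))
      kw <- c(kw, sprintf("$P%dS", i), stain_names[i])
  }
  delim <- "/"
  text <- paste0(delim, paste(kw, collapse = delim), delim)
  text_start <- 58L
  text_end <- text_start + nchar(text) - 1L
  data_start <- text_end + 1L
  data_end <- data_start + n_par * n_tot * size - 1L
  header <- sprintf("%-6s    %8d%8d%8d%8d%8d%8d", version, text_start,
                    text_end, data_start, data_end, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  writeBin(as.vector(t(data)), con, size = size, endian = endian)
  invisible(path)
}
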