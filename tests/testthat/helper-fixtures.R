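# Shared fixtures. Built once per test run; all generators are deterministic.

fx_pair <- make_long_short_pair()
fx_rec <- make_receptor_fixture()

# minimal atom-table structure for geometric oracles
mk_struct <- function(x, y, z, chain = "A", name = NULL, resno = NULL,
                      element = "C") {
  n <- length(x)
  structure3d(data.frame(
    name = name %||% paste0("S", seq_len(n)), element = element,
    x = x, y = y, z = z,
    resno = resno %||% seq_len(n), resid = "ALA",
    chain = rep_len(chain, n), stringsAsFactors = FALSE))
}

# independent brute-force clash count (double loop) used as an oracle
brute_clashes <- function(a, b, cutoff = 2.5) {
  A <- coords(a, heavy_only = TRUE); B <- coords(b, heavy_only = TRUE)
  n <- 0L
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    if (sqrt(sum((A[i, ] - B[j, ])^2)) < cutoff) n <- n + 1L
  }
  n
}

# independent contact-pair oracle (double loop over residues)
brute_contacts <- function(a, b, cutoff = 4.5) {
  A <- a$atoms[a$atoms$is_heavy, ]; B <- b$atoms[b$atoms$is_heavy, ]
  out <- list()
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    d <- sqrt((A$x[i] - B$x[j])^2 + (A$y[i] - B$y[j])^2 + (A$z[i] - B$z[j])^2)
    if (d < cutoff)
      out[[length(out) + 1]] <- c(A$chain[i], A$resno[i], B$chain[j], B$resno[j])
  }
  if (length(out) == 0)
    return(data.frame(chain_a = character(), resno_a = integer(),
                      chain_b = character(), resno_b = integer()))
  m <- unique(do.call(rbind, out))
  d <- data.frame(chain_a = m[, 1], resno_a = as.integer(m[, 2]),
                  chain_b = m[, 3], resno_b = as.integer(m[, 4]),
                  stringsAsFactors = FALSE)
  d <- d[order(d$chain_a, d$resno_a, d$chain_b, d$resno_b), ]
  rownames(d) <- NULL
  d
}

# random rigid transform
random_transform <- function() {
  A <- matrix(rnorm(9), 3)
  qr_ <- qr(A)
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  rigid_transform(Q, rnorm(3, sd = 10))
}

# circular angle error in degrees
ang_err <- function(a, b) min(abs(a - b) %% 360, 360 - abs(a - b) %% 360)

# re-score an alignment under the package's gap convention
rescore_alignment <- function(al_a, al_b, M, gap_open = 12, gap_extend = 2) {
  ca <- strsplit(al_a, "")[[1]]; cb <- strsplit(al_b, "")[[1]]
  s <- 0; in_gap_a <- FALSE; in_gap_b <- FALSE
  for (k in seq_along(ca)) {
    if (ca[k] == "-") {
      s <- s - if (in_gap_a) gap_extend else gap_open
      in_gap_a <- TRUE; in_gap_b <- FALSE
    } else if (cb[k] == "-") {
      s <- s - if (in_gap_b) gap_extend else gap_open
      in_gap_b <- TRUE; in_gap_a <- FALSE
    } else {
      s <- s + M[ca[k], cb[k]]
      in_gap_a <- FALSE; in_gap_b <- FALSE
    }
  }
  s
}

# brute-force optimal global affine-gap alignment score by enumeration of all
# monotone alignment paths (tiny sequences only)
brute_align_score <- function(a, b, M, gap_open = 12, gap_extend = 2) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, sc, last) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, sc); return(invisible())
    }
    if (i <= length(ca) && j <= length(cb))
      rec(i + 1, j + 1, sc + M[ca[i], cb[j]], "m")
    if (i <= length(ca))
      rec(i + 1, j, sc - if (identical(last, "a")) gap_extend else gap_open, "a")
    if (j <= length(cb))
      rec(i, j + 1, sc - if (identical(last, "b")) gap_extend else gap_open, "b")
  }
  rec(1, 1, 0, "")
  best
}

# exact Kruskal-Wallis permutation p-value by full enumeration of group
# assignments (total n small)
kw_exact_p <- function(groups) {
  vals <- unlist(groups, use.names = FALSE)
  sizes <- vapply(groups, length, 0L)
  obs <- kruskal_wallis(groups)$statistic
  idx <- seq_along(vals)
  cnt <- 0L; tot <- 0L
  rec <- function(remaining, gi, assign) {
    if (gi == length(sizes)) {
      assign[remaining] <- gi
      tot <<- tot + 1L
      h <- kruskal_wallis(split(vals, assign))$statistic
      if (h >= obs - 1e-12) cnt <<- cnt + 1L
      return(invisible())
    }
    for (cmb in utils::combn(remaining, sizes[gi], simplify = FALSE)) {
      a2 <- assign; a2[cmb] <- gi
      rec(setdiff(remaining, cmb), gi + 1L, a2)
    }
  }
  rec(idx, 1L, integer(length(vals)))
  cnt / tot
}
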