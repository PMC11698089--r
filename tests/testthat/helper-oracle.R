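# Independent oracles used across the suite. These deliberately re-derive
# masses and matching by brute force, separate from the package's code paths.

ORACLE_AA <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
ORACLE_PROTON <- 1.007276
ORACLE_WATER <- 18.010565

oracle_peptide_mass <- function(seq) {
  sum(ORACLE_AA[strsplit(seq, "")[[1]]]) + ORACLE_WATER
}

# brute-force digest: every contiguous span bounded by cut sites, counting
# the internal cut sites it skips
oracle_digest <- function(seq, max_missed) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  is_cut <- function(i) i >= 1 && i < n && s[i] %in% c("K", "R") && s[i + 1] != "P"
  cut_after <- vapply(seq_len(n), function(i)
    i == n || is_cut(i), logical(1))
  out <- character(0)
  for (a in seq_len(n)) for (b in a:n) {
    if (a > 1 && !(s[a - 1] %in% c("K", "R") && s[a] != "P")) next
    if (!(b == n || (s[b] %in% c("K", "R") && s[b + 1] != "P"))) next
    internal <- if (b > a) sum(vapply((a):(b - 1), is_cut, logical(1))) else 0
    if (internal <= max_missed) out <- c(out, paste(s[a:b], collapse = ""))
  }
  sort(unique(out))
}

# smallest y index containing a residue, by scanning every y span (up to
# y_L, the full chain, which contains the N-terminal residue)
oracle_min_y <- function(start_res, end_res, residue) {
  L <- end_res - start_res + 1
  for (idx in 1:L) {
    span <- (end_res - idx + 1):end_res
    if (residue %in% span) return(idx)
  }
  stop("residue not contained in any y span")
}

# theoretical singly charged b/y m/z for a peptide with adducts at given
# residue numbers, derived from the oracle mass table only
oracle_by_ions <- function(seq, start_res, sites, delta) {
  s <- strsplit(seq, "")[[1]]
  L <- length(s)
  end_res <- start_res + L - 1
  rows <- list()
  for (i in 1:(L - 1)) {
    b_span <- start_res:(start_res + i - 1)
    y_span <- (end_res - i + 1):end_res
    b_m <- sum(ORACLE_AA[s[1:i]]) + sum(sites %in% b_span) * delta
    y_m <- sum(ORACLE_AA[s[(L - i + 1):L]]) + ORACLE_WATER +
      sum(sites %in% y_span) * delta
    rows[[length(rows) + 1]] <- data.frame(
      series = c("b", "y"), index = i,
      n_add = c(sum(sites %in% b_span), sum(sites %in% y_span)),
      mz = c(b_m + ORACLE_PROTON, y_m + ORACLE_PROTON))
  }
  do.call(rbind, rows)
}

# exhaustive localization rescoring: for every site combination count the
# matched site-determining ions (ions whose adduct count varies across
# combinations), intensity tiebreak; returns the set of best combinations
oracle_localize <- function(spec_mz, spec_int, seq, start_res, n_adducts,
                            tol_ppm, delta) {
  L <- nchar(seq)
  positions <- start_res:(start_res + L - 1)
  combos <- utils::combn(positions, n_adducts, simplify = FALSE)
  ions <- lapply(combos, function(S) oracle_by_ions(seq, start_res, S, delta))
  nadd <- sapply(ions, `[[`, "n_add")
  site_det <- apply(nadd, 1, function(r) length(unique(r)) > 1)
  score <- numeric(length(combos)); sint <- numeric(length(combos))
  for (k in seq_along(combos)) {
    for (i in which(site_det)) {
      m <- ions[[k]]$mz[i]
      j <- which(abs(spec_mz - m) / m * 1e6 <= tol_ppm)
      if (length(j)) {
        score[k] <- score[k] + 1
        sint[k] <- sint[k] + max(spec_int[j])
      }
    }
  }
  best <- which(score == max(score))
  if (length(best) > 1) best <- best[sint[best] >= max(sint[best]) - 1e-9]
  combos[best]
}

# convenience: an MS2 spectrum (list with mz/intensity) holding exactly the
# given theoretical ions, via the oracle mass table
oracle_spectrum <- function(seq, start_res, sites, delta,
                            keep = function(series, index) TRUE) {
  tab <- oracle_by_ions(seq, start_res, sites, delta)
  sel <- mapply(keep, tab$series, tab$index)
  list(mz = tab$mz[sel], intensity = rep(100, sum(sel)))
}

rand_peptide_seq <- function(len) {
  paste(sample(names(ORACLE_AA), len, replace = TRUE), collapse = "")
}
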