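# Plan7-lite profile HMMs: match/insert/delete states estimated from a seed
# alignment, Smith-Waterman-style local Viterbi scoring in bits, and Gumbel
# E-value calibration by the method of moments. One best domain per protein
# per family; no multi-hit (J) state; insert emissions equal the background,
# so inserted residues contribute only their transition terms.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.seed_matrix <- function(rows) {
  if (length(rows) < 2L) stop("seed alignment needs >= 2 rows")
  if (length(unique(nchar(rows))) != 1L)
    stop("seed alignment rows must have equal length")
  m <- do.call(rbind, strsplit(toupper(rows), ""))
  m[m == "."] <- "-"
  bad <- setdiff(unique(as.vector(m)), c(AA_ALPHABET, "-", "X"))
  if (length(bad))
    stop("seed alignment contains invalid characters: ",
         paste(bad, collapse = ", "))
  m
}

#' Build a profile HMM from a seed alignment
#'
#' Match states are the alignment columns whose gap fraction is below
#' `gap_fraction_max`. Match emissions are additively smoothed column counts,
#' `(count + pseudocount) / (n_nongap + 20 * pseudocount)`; transition
#' probabilities come from the observed per-row state paths with the same
#' smoothing; the background is the smoothed overall residue frequency of
#' the seed, and insert states emit the background.
#'
#' @param seed List with `family` (string) and `rows` (equal-length gapped
#'   protein strings, gap `-` or `.`).
#' @param gap_fraction_max Columns with a gap fraction at or above this are
#'   insert columns (default 0.5).
#' @param pseudocount Additive smoothing constant (default 1).
#' @return A `profile_hmm` object: family, `L`, `match_emissions` (L x 20),
#'   `insert_emissions`, `background`, per-state transition matrices
#'   (`t_m`: MM/MI/MD, `t_i`: IM/II, `t_d`: DM/DD), and `gumbel_mu` /
#'   `gumbel_lambda` (NA until [calibrate_evalue()]).
#' @export
build_profile <- function(seed, gap_fraction_max = 0.5, pseudocount = 1.0) {
  stopifnot(gap_fraction_max > 0, gap_fraction_max < 1, pseudocount > 0)
  m <- .seed_matrix(seed$rows)
  nrows <- nrow(m)
  gapfrac <- colMeans(m == "-")
  match_cols <- which(gapfrac < gap_fraction_max)
  L <- length(match_cols)
  if (L == 0L) stop("no column passes the gap threshold (L = 0)")

  # background: smoothed overall residue frequency (X ignored)
  res <- as.vector(m)
  res <- res[res %in% AA_ALPHABET]
  bg_counts <- table(factor(res, levels = AA_ALPHABET))
  background <- (as.numeric(bg_counts) + pseudocount) /
    (length(res) + 20 * pseudocount)
  names(background) <- AA_ALPHABET

  match_emissions <- matrix(0, L, 20, dimnames = list(NULL, AA_ALPHABET))
  for (k in seq_len(L)) {
    col <- m[, match_cols[k]]
    col <- col[col %in% AA_ALPHABET]
    cnt <- table(factor(col, levels = AA_ALPHABET))
    match_emissions[k, ] <- (as.numeric(cnt) + pseudocount) /
      (length(col) + 20 * pseudocount)
  }

  # per-row state paths over (M_j, I_j, D_j); count transitions
  cMM <- cMI <- cMD <- cIM <- cII <- cDM <- cDD <- numeric(L)
  is_match <- seq_len(ncol(m)) %in% match_cols
  midx <- cumsum(is_match)               # match index of each column
  for (r in seq_len(nrows)) {
    prev <- NULL                          # c(type, j)
    for (cidx in seq_len(ncol(m))) {
      ch <- m[r, cidx]
      if (is_match[cidx]) {
        st <- c(if (ch == "-") "D" else "M", midx[cidx])
      } else {
        if (ch == "-") next
        st <- c("I", midx[cidx])          # insert after match state midx
      }
      if (!is.null(prev)) {
        j <- as.integer(prev[2])
        key <- paste0(prev[1], st[1])
        if (j >= 1L) {
          switch(key,
                 MM = cMM[j] <- cMM[j] + 1, MI = cMI[j] <- cMI[j] + 1,
                 MD = cMD[j] <- cMD[j] + 1, IM = cIM[j] <- cIM[j] + 1,
                 II = cII[j] <- cII[j] + 1, DM = cDM[j] <- cDM[j] + 1,
                 DD = cDD[j] <- cDD[j] + 1)
        }
      }
      prev <- st
    }
  }
  pc <- pseudocount
  t_m <- cbind(MM = cMM + pc, MI = cMI + pc, MD = cMD + pc)
  t_m <- t_m / rowSums(t_m)
  t_i <- cbind(IM = cIM + pc, II = cII + pc)
  t_i <- t_i / rowSums(t_i)
  t_d <- cbind(DM = cDM + pc, DD = cDD + pc)
  t_d <- t_d / rowSums(t_d)

  structure(list(
    family = seed$family, L = L,
    match_emissions = match_emissions,
    insert_emissions = background,
    background = background,
    t_m = t_m, t_i = t_i, t_d = t_d,
    gumbel_mu = NA_real_, gumbel_lambda = NA_real_
  ), class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("profile_hmm '%s': L = %d, %s\n", x$family, x$L,
              if (is.na(x$gumbel_lambda)) "uncalibrated"
              else sprintf("Gumbel(mu = %.2f, lambda = %.3f)",
                           x$gumbel_mu, x$gumbel_lambda)))
  invisible(x)
}

.NEG <- -1e30  # sentinel below any legal log-odds score

.encode_protein <- function(protein) {
  idx <- match(strsplit(toupper(protein), "")[[1]], AA_ALPHABET)
  idx  # NA for X/unknown -> background emission (log-odds 0)
}

#' Local Viterbi score of a protein against a profile
#'
#' Best local path log-odds in bits: the alignment may enter at any match
#' state and exit at any match state for free; flanking residues are emitted
#' by the background and contribute nothing. The score of a path is
#' `sum log2(P_emit / background) + sum log2(P_transition)`; insert states
#' emit the background, so inserts cost only their transitions. Residues
#' outside the 20-letter alphabet (X) score 0 everywhere.
#'
#' @param profile A `profile_hmm`.
#' @param protein Non-empty amino-acid string.
#' @return List with `bit_score`, `ali_start`, `ali_end` (0-based half-open
#'   protein coordinates of the aligned span).
#' @export
viterbi_score <- function(profile, protein) {
  if (!nzchar(protein)) stop("empty protein")
  L <- profile$L
  n <- nchar(protein)
  xi <- .encode_protein(protein)

  lbg <- log2(profile$background)
  lem <- log2(profile$match_emissions)       # L x 20
  eod <- sweep(lem, 2, lbg)                  # emission log-odds
  # transition log-odds; index j = transition out of state j
  tMM <- c(log2(profile$t_m[, "MM"])[-L], .NEG)
  tMI <- c(log2(profile$t_m[, "MI"])[-L], .NEG)
  tMD <- c(log2(profile$t_m[, "MD"])[-L], .NEG)
  tIM <- c(log2(profile$t_i[, "IM"])[-L], .NEG)
  tII <- c(log2(profile$t_i[, "II"])[-L], .NEG)
  tDM <- c(log2(profile$t_d[, "DM"])[-L], .NEG)
  tDD <- c(log2(profile$t_d[, "DD"])[-L], .NEG)

  VM <- rep(.NEG, L); VI <- rep(.NEG, L); VD <- rep(.NEG, L)
  SM <- integer(L); SI <- integer(L); SD <- integer(L)
  best <- .NEG; best_start <- 0L; best_end <- 0L

  for (r in seq_len(n)) {
    e_r <- if (is.na(xi[r])) numeric(L) else eod[, xi[r]]
    # shifted predecessors (j-1), consumed r-1 residues
    pM <- c(.NEG, VM[-L] + tMM[-L])
    pI <- c(.NEG, VI[-L] + tIM[-L])
    pD <- c(.NEG, VD[-L] + tDM[-L])
    sM <- c(0L, SM[-L]); sI <- c(0L, SI[-L]); sD <- c(0L, SD[-L])
    entry <- rep(0, L)
    cand <- cbind(entry, pM, pI, pD)
    pick <- max.col(cand, ties.method = "first")
    base <- cand[cbind(seq_len(L), pick)]
    nVM <- e_r + base
    nSM <- ifelse(pick == 1L, r - 1L,
                  ifelse(pick == 2L, sM, ifelse(pick == 3L, sI, sD)))
    # inserts (consume r, stay at j)
    a <- VM + tMI; b <- VI + tII
    nVI <- pmax(a, b)
    nSI <- ifelse(a >= b, SM, SI)
    VM <- nVM; SM <- as.integer(nSM)
    VI <- nVI; SI <- as.integer(nSI)
    # delete chain along j within this row (no residues consumed)
    B <- VM + tMD
    if (L > 1L) {
      ctdd <- cumsum(c(0, tDD[-L]))        # ctdd[j] = sum of tDD[1..j-1]
      Badj <- B - ctdd
      run <- cummax(Badj)
      newmax <- Badj >= c(.NEG * 2, run[-L])
      runidx <- cummax(ifelse(Badj == run, seq_len(L), 0L))
      VD <- c(.NEG, run[-L] + ctdd[-1])
      SD <- as.integer(c(0L, SM[pmax(runidx[-L], 1L)]))
    } else {
      VD <- .NEG; SD <- 0L
    }
    m_r <- max(VM)
    if (m_r > best) {
      j <- which.max(VM)
      best <- m_r; best_start <- SM[j]; best_end <- r
    }
  }
  list(bit_score = best, ali_start = best_start, ali_end = best_end)
}

#' Calibrate a profile's Gumbel E-value parameters
#'
#' Scores the profile against `n_random` i.i.d. null-distributed proteins
#' of length `mean_len` and fits a Gumbel distribution by the method of
#' moments: `lambda = pi / (sd * sqrt(6))`,
#' `mu = mean - gamma / lambda` (gamma = Euler-Mascheroni). The E-value of a
#' score `s` against a database of `N` sequences is
#' `N * exp(-lambda * (s - mu))`, clamped to `[0, N]`.
#'
#' The null composition defaults to uniform over the 20 amino acids rather
#' than the profile's seed-derived background: the null models the database
#' being scanned, and a small seed's residue frequencies are a biased
#' estimate of it, which makes E-values anti-conservative whenever the
#' database composition differs from the seed's.
#'
#' @param profile A `profile_hmm`.
#' @param n_random Number of random proteins (>= 100).
#' @param mean_len Length of each random protein.
#' @param rng_seed Integer seed; calibration is deterministic given it.
#' @param null_freqs Length-20 residue distribution of the null proteins
#'   (default uniform).
#' @return The profile with `gumbel_mu` and `gumbel_lambda` set.
#' @export
calibrate_evalue <- function(profile, n_random = 200L, mean_len = 100L,
                             rng_seed = 1L, null_freqs = rep(1 / 20, 20)) {
  stopifnot(n_random >= 100L, mean_len >= 1L, length(null_freqs) == 20L)
  set.seed(rng_seed)
  scores <- vapply(seq_len(n_random), function(i) {
    p <- paste(sample(AA_ALPHABET, mean_len, replace = TRUE,
                      prob = null_freqs), collapse = "")
    viterbi_score(profile, p)$bit_score
  }, 0)
  s <- sd(scores)
  if (!is.finite(s) || s == 0) stop("degenerate score variance in calibration")
  lambda <- pi / (s * sqrt(6))
  mu <- mean(scores) - 0.57721566490153286 / lambda
  profile$gumbel_mu <- mu
  profile$gumbel_lambda <- lambda
  profile
}

#' E-value of a bit score
#'
#' @param profile Calibrated `profile_hmm`.
#' @param bit_score Numeric score(s) in bits.
#' @param n_db Number of sequences in the scanned database.
#' @return E-value(s) in `[0, n_db]`, strictly decreasing in the score
#'   inside the clamp.
#' @export
evalue <- function(profile, bit_score, n_db) {
  if (is.na(profile$gumbel_lambda)) stop("profile is not calibrated")
  pmin(n_db, pmax(0, n_db * exp(-profile$gumbel_lambda *
                                  (bit_score - profile$gumbel_mu))))
}

#' Scan proteins against a set of profiles
#'
#' Reports every (protein, family) domain hit with an E-value below `e_max`,
#' with `N` = number of scanned proteins. One best domain per protein per
#' family.
#'
#' @param proteins data.frame with `protein_id` and `protein` columns.
#' @param profiles List of calibrated `profile_hmm` objects.
#' @param e_max E-value threshold (default 0.01).
#' @return data.frame of hits (`protein_id`, `family`, `bit_score`,
#'   `e_value`, `ali_start`, `ali_end`) sorted by protein id, ascending
#'   E-value, family.
#' @export
scan_proteins <- function(proteins, profiles, e_max = 0.01) {
  empty <- data.frame(protein_id = character(), family = character(),
                      bit_score = numeric(), e_value = numeric(),
                      ali_start = integer(), ali_end = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(proteins) == 0L || length(profiles) == 0L) return(empty)
  for (pr in profiles)
    if (is.na(pr$gumbel_lambda))
      stop("uncalibrated profile: ", pr$family)
  N <- nrow(proteins)
  rows <- list()
  for (i in seq_len(N)) {
    for (pr in profiles) {
      v <- viterbi_score(pr, proteins$protein[i])
      e <- evalue(pr, v$bit_score, N)
      if (e < e_max) {
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = proteins$protein_id[i], family = pr$family,
          bit_score = v$bit_score, e_value = e,
          ali_start = v$ali_start, ali_end = v$ali_end,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$protein_id, out$e_value, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialize a profile to versioned JSON
#' @param profile A `profile_hmm`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile_json <- function(profile, path) {
  obj <- unclass(profile)
  obj$format_version <- 1L
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a profile from JSON written by [write_profile_json()]
#' @param path Input path.
#' @return A `profile_hmm`.
#' @export
read_profile_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version) || obj$format_version != 1L)
    stop("unsupported profile format version")
  named <- function(m, nm) { m <- as.matrix(m); colnames(m) <- nm; m }
  structure(list(
    family = obj$family, L = as.integer(obj$L),
    match_emissions = named(obj$match_emissions, AA_ALPHABET),
    insert_emissions = stats::setNames(unlist(obj$insert_emissions), AA_ALPHABET),
    background = stats::setNames(unlist(obj$background), AA_ALPHABET),
    t_m = named(obj$t_m, c("MM", "MI", "MD")),
    t_i = named(obj$t_i, c("IM", "II")),
    t_d = named(obj$t_d, c("DM", "DD")),
    gumbel_mu = obj$gumbel_mu, gumbel_lambda = obj$gumbel_lambda
  ), class = "profile_hmm")
}

#' Read a seed alignment from aligned FASTA or Stockholm
#'
#' @param path Path to the alignment file.
#' @param family Family name; defaults to the file name without extension.
#' @param format `"fasta"` or `"stockholm"` (guessed from the extension).
#' @return Seed list with `family` and `rows` for [build_profile()].
#' @export
read_seed_alignment <- function(path, family = NULL, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(sto|stk|stockholm)$", path)) "stockholm" else "fasta"
  }
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  rows <- as.character(Biostrings::unmasked(aln))
  if (is.null(family))
    family <- sub("\\.[^.]*$", "", basename(path))
  list(family = family, rows = unname(rows))
}

#' Write a seed alignment as aligned FASTA
#' @param seed Seed list (`family`, `rows`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_seed_alignment <- function(seed, path) {
  x <- Biostrings::AAStringSet(seed$rows)
  names(x) <- sprintf("%s_seed%02d", seed$family, seq_along(seed$rows))
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}
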