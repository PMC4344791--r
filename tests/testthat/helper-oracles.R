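# Independent oracles used by the unit and acceptance tests. Each one
# recomputes the quantity under test by a different mechanism than the
# implementation (exhaustive enumeration, straightforward DP, replay).

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
NT4 <- c("A", "C", "G", "T")

rand_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")
rand_nt <- function(n) paste(sample(NT4, n, replace = TRUE), collapse = "")

# --- exhaustive Viterbi path enumeration (profile_hmm oracle) -------------
# Enumerates every legal local state path (enter at any match state, exit at
# any match state) by depth-first search and returns the best bit score.
enum_viterbi <- function(profile, protein) {
  L <- profile$L
  n <- nchar(protein)
  x <- match(strsplit(protein, "")[[1]], AA20)
  eod <- log2(sweep(profile$match_emissions, 2, profile$background, "/"))
  tm <- log2(profile$t_m); ti <- log2(profile$t_i); td <- log2(profile$t_d)
  best <- -Inf
  rec <- function(type, j, r, sc) {
    if (type == "M" && sc > best) best <<- sc
    if (j >= L) return(invisible())
    if (type == "M") {
      if (r < n) {
        e <- if (is.na(x[r + 1])) 0 else eod[j + 1, x[r + 1]]
        rec("M", j + 1, r + 1, sc + tm[j, "MM"] + e)
        rec("I", j, r + 1, sc + tm[j, "MI"])
      }
      rec("D", j + 1, r, sc + tm[j, "MD"])
    } else if (type == "I") {
      if (r < n) {
        rec("I", j, r + 1, sc + ti[j, "II"])
        e <- if (is.na(x[r + 1])) 0 else eod[j + 1, x[r + 1]]
        rec("M", j + 1, r + 1, sc + ti[j, "IM"] + e)
      }
    } else {
      rec("D", j + 1, r, sc + td[j, "DD"])
      if (r < n) {
        e <- if (is.na(x[r + 1])) 0 else eod[j + 1, x[r + 1]]
        rec("M", j + 1, r + 1, sc + td[j, "DM"] + e)
      }
    }
  }
  for (r0 in 0:(n - 1)) for (j0 in 1:L) {
    e <- if (is.na(x[r0 + 1])) 0 else eod[j0, x[r0 + 1]]
    rec("M", j0, r0 + 1, e)
  }
  unname(best)
}

# random tiny profile for the oracle grid
random_toy_profile <- function() {
  repeat {
    L <- sample(1:4, 1)
    nr <- sample(2:4, 1)
    rows <- replicate(nr, paste(
      sample(c(AA20, "-"), L + sample(0:2, 1), replace = TRUE,
             prob = c(rep(1, 20), 3)), collapse = ""))
    p <- tryCatch(build_profile(list(family = "TOY", rows = rows)),
                  error = function(e) NULL)
    if (!is.null(p)) return(p)
  }
}

# --- straightforward affine-gap local DP (alignment score oracle) ---------
# Gotoh three-state DP; a gap of length k costs gap_open + k * gap_extend.
gotoh_local_score <- function(a, b, match = 1, mismatch = -2,
                              gap_open = 2, gap_extend = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  go <- gap_open + gap_extend
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i, j - 1] - go, E[i, j - 1] - gap_extend)
    F[i, j] <- max(H[i - 1, j] - go, F[i - 1, j] - gap_extend)
    s <- if (A[i - 1] == B[j - 1]) match else mismatch
    H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}

# --- greedy clustering replay (redundancy oracle) -------------------------
# All-pairs identity matrix plus an independent replay of the documented
# greedy order, with no prefilter.
replay_cluster <- function(records, threshold, alphabet) {
  ord <- order(-nchar(records), seq_along(records))
  ids <- names(records)[ord]
  seqs <- unname(records[ord])
  n <- length(seqs)
  idm <- matrix(1, n, n)
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n)
    idm[i, j] <- idm[j, i] <- pairwise_identity(seqs[i], seqs[j], alphabet)
  reps <- integer(0); members <- list()
  for (i in seq_len(n)) {
    hit <- reps[idm[reps, i] >= threshold]
    if (length(hit)) {
      ci <- match(hit[1], reps)
      members[[ci]] <- c(members[[ci]], ids[i])
    } else {
      reps <- c(reps, i)
      members[[length(reps)]] <- character()
    }
  }
  lapply(seq_along(reps), function(ci)
    list(representative_id = ids[reps[ci]], member_ids = members[[ci]],
         threshold = threshold))
}

cluster_signature <- function(clusters) {
  lapply(clusters, function(cl) c(cl$representative_id, sort(cl$member_ids)))
}

# small related protein family for profile tests
related_rows <- function(n_rows = 6, len = 35, n_var = 10) {
  cons <- sample(AA20, len, replace = TRUE)
  replicate(n_rows, {
    r <- cons
    i <- sample(len, n_var)
    r[i] <- sample(AA20, n_var, replace = TRUE)
    paste(r, collapse = "")
  })
}
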