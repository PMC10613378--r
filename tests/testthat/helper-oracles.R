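# Independent brute-force oracles and small fixture builders. The oracles
# deliberately use naive enumeration (no Matrix/igraph) so they are
# independent of the implementation paths they check.

# shared-patient projection by explicit pair/patient loops
brute_projection <- function(z, scheme = "shared-count") {
  n <- nrow(z)
  A <- matrix(0, n, n, dimnames = list(rownames(z), rownames(z)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- 0
    for (k in seq_len(ncol(z))) {
      if (z[i, k] > 0 && z[j, k] > 0) {
        s <- s + if (scheme == "shared-count") 1 else sqrt(z[i, k] * z[j, k])
      }
    }
    A[i, j] <- s
  }
  A
}

# unnormalized geodesic betweenness by exhaustive shortest-path enumeration
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  bet <- numeric(n)
  paths_between <- function(s, t) {
    res <- list()
    best <- Inf
    rec <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        if (length(path) < best) {
          best <<- length(path)
          res <<- list(path)
        } else if (length(path) == best) res[[length(res) + 1L]] <<- path
        return(invisible(NULL))
      }
      if (length(path) >= best) return(invisible(NULL))
      for (w in which(adj[v, ] > 0)) if (!(w %in% path)) rec(c(path, w))
    }
    rec(s)
    res
  }
  if (n < 3) return(bet)
  for (s in seq_len(n - 1)) for (t in seq((s + 1), n)) {
    ps <- paths_between(s, t)
    if (length(ps) == 0) next
    for (p in ps) {
      for (v in setdiff(p, c(s, t))) bet[v] <- bet[v] + 1 / length(ps)
    }
  }
  bet
}

# random symmetric 0/1 adjacency with zero diagonal
random_adjacency <- function(n, p = 0.4) {
  M <- matrix(0, n, n)
  M[upper.tri(M)] <- as.numeric(runif(n * (n - 1) / 2) < p)
  M + t(M)
}

# random small encounter-count matrix (physicians x patients)
random_counts <- function(n_phys, n_pat, p = 0.4, max_enc = 4) {
  z <- matrix(rbinom(n_phys * n_pat, 1, p) *
                sample.int(max_enc, n_phys * n_pat, replace = TRUE),
              n_phys, n_pat,
              dimnames = list(paste0("p", seq_len(n_phys)),
                              paste0("t", seq_len(n_pat))))
  z
}

# billing records from an encounter-count matrix placed in one hospital
records_from_counts <- function(z, hospital = "h1",
                                date = as.Date("2019-06-01")) {
  idx <- which(z > 0, arr.ind = TRUE)
  n <- z[idx]
  data.frame(physician_id = rep(rownames(z)[idx[, 1]], n),
             patient_id = rep(colnames(z)[idx[, 2]], n),
             hospital_id = hospital, date = date,
             stringsAsFactors = FALSE)
}

# attribution table for fixtures built directly from matrices
make_attribution <- function(ids, primary, volumes = NULL) {
  out <- data.frame(physician_id = ids, primary_hospital_id = primary,
                    total_encounters = NA_real_, n_sites = 1L,
                    n_nonprimary = 0L, stringsAsFactors = FALSE)
  if (!is.null(volumes)) {
    out$n_sites <- as.integer(rowSums(volumes > 0))
    out$n_nonprimary <- out$n_sites - 1L
    attr(out, "volumes") <- volumes
  }
  class(out) <- c("physician_attribution", "data.frame")
  out
}

# a small, fast study configuration for pipeline-level tests
small_config <- function(seed = 1, ...) {
  sim_config(n_hospitals = 8L, n_steps = 4L,
             physicians_per_hospital = c(4L, 6L),
             patients_per_hospital = c(10L, 16L),
             seed = seed, ...)
}
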