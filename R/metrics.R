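# Network metrics: degree, betweenness centrality, density, per-hospital
# subnetwork density, Shannon diversity of billing shares, and the
# shared-patient threshold robustness sweep.

#' Participation rate from recruitment counts
#'
#' The percentage of invited physicians who agreed to participate, rounded
#' to two decimals as reported.
#'
#' @param n_participated,n_invited recruitment counts.
#' @return percentage in \[0, 100\].
#' @examples
#' participation_rate(163, 348)  # 46.84
#' @export
participation_rate <- function(n_participated, n_invited) {
  if (n_invited <= 0 || n_participated < 0 || n_participated > n_invited)
    stopf("participation_rate: counts must satisfy 0 <= participated <= invited")
  round(100 * n_participated / n_invited, 2)
}

#' Node degree of a binary network
#'
#' Number of edges directly connecting each physician to others (row sums
#' of the binary adjacency matrix).
#'
#' @param B a [binarize()] network.
#' @return named integer vector of degrees.
#' @export
net_degree <- function(B) {
  stopifnot(inherits(B, "binary_network"))
  setNames(as.integer(round(Matrix::rowSums(B$edges))), B$physicians)
}

#' Within- and across-hospital degree split
#'
#' Splits each physician's degree into ties to peers sharing the same
#' primary hospital and ties to peers attributed elsewhere.
#'
#' @param B a [binarize()] network.
#' @param attribution an [attribute_physicians()] table aligned to `B`.
#' @return data.frame with physician_id, degree, within_degree,
#'   across_degree.
#' @export
degree_split <- function(B, attribution) {
  dec <- decompose_network(B, attribution)
  data.frame(physician_id = B$physicians,
             degree = as.integer(round(Matrix::rowSums(B$edges))),
             within_degree = as.integer(round(Matrix::rowSums(dec$B_wi))),
             across_degree = as.integer(round(Matrix::rowSums(dec$B_ac))),
             stringsAsFactors = FALSE)
}

#' Betweenness centrality
#'
#' Unnormalized geodesic betweenness on the undirected, unweighted graph:
#' the extent to which a physician lies on shortest paths between other
#' pairs of physicians. Pairs in different components contribute nothing.
#'
#' @param B a [binarize()] network.
#' @return named numeric vector.
#' @export
net_betweenness <- function(B) {
  stopifnot(inherits(B, "binary_network"))
  g <- as_igraph(B)
  b <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  setNames(as.numeric(b), B$physicians)
}

#' Network density
#'
#' Proportion of directly connected pairs out of all possible pairs,
#' edges / choose(n, 2).
#'
#' @param B a [binarize()] network.
#' @return a single proportion; `NA` (with a warning) when n < 2.
#' @export
net_density <- function(B) {
  stopifnot(inherits(B, "binary_network"))
  n <- length(B$physicians)
  if (n < 2L) {
    warning("net_density: undefined for fewer than 2 nodes")
    return(NA_real_)
  }
  n_edges <- length(B$edges@x) / 2
  n_edges / choose(n, 2)
}

#' Edge density of each hospital's primary-attributed subnetwork
#'
#' Induces, for each hospital, the subgraph on the physicians whose primary
#' billing hospital it is, and reports that subgraph's density. Hospitals
#' with fewer than two attributed physicians are excluded from the summary.
#'
#' @param B a [binarize()] network.
#' @param attribution an [attribute_physicians()] table.
#' @return list with `per_hospital` (hospital_id, n_physicians, density)
#'   and `summary` (mean, median, sd over hospitals with >= 2 physicians),
#'   plus `excluded` hospital ids.
#' @export
subnetwork_density <- function(B, attribution) {
  stopifnot(inherits(B, "binary_network"))
  if (!all(B$physicians %in% attribution$physician_id))
    stopf("subnetwork_density: unattributed physician(s) present")
  prim <- attribution$primary_hospital_id[
    match(B$physicians, attribution$physician_id)]
  hosp <- sort(unique(prim))
  dens <- rep(NA_real_, length(hosp))
  nphy <- integer(length(hosp))
  for (h in seq_along(hosp)) {
    members <- which(prim == hosp[h])
    nphy[h] <- length(members)
    if (length(members) >= 2L) {
      sub <- B$edges[members, members, drop = FALSE]
      dens[h] <- (sum(sub) / 2) / choose(length(members), 2)
    }
  }
  per_hospital <- data.frame(hospital_id = hosp, n_physicians = nphy,
                             density = dens, stringsAsFactors = FALSE)
  ok <- !is.na(dens)
  list(per_hospital = per_hospital,
       summary = c(mean = mean(dens[ok]), median = median(dens[ok]),
                   sd = sd(dens[ok])),
       excluded = hosp[!ok])
}

#' Shannon diversity of hospital billing shares
#'
#' H = -sum_l p_l ln p_l over hospitals with positive volume, where p_l is
#' the proportion of a physician's encounters billed at hospital l (natural
#' log; 0 * ln 0 taken as 0). A single-site physician scores 0; an equal
#' split over R hospitals scores ln(R).
#'
#' @param volumes either a physician-by-hospital volume matrix (as attached
#'   to [attribute_physicians()]) or a single nonnegative volume vector.
#' @return named numeric vector of H values (nats), or a single value for a
#'   vector input.
#' @export
shannon_diversity <- function(volumes) {
  one <- function(v) {
    if (any(v < 0) || sum(v) <= 0)
      stopf("shannon_diversity: volumes must be nonnegative with positive sum")
    p <- v[v > 0] / sum(v)
    -sum(p * log(p)) + 0  # + 0 normalizes IEEE negative zero
  }
  if (is.matrix(volumes)) {
    setNames(apply(volumes, 1L, one), rownames(volumes))
  } else one(as.numeric(volumes))
}

#' Per-physician network metric table
#'
#' Combines degree (total and within/across split), betweenness centrality,
#' Shannon diversity, and site counts into one table.
#'
#' @param B a [binarize()] network.
#' @param attribution an [attribute_physicians()] table.
#' @return data.frame keyed by physician_id.
#' @export
network_metrics <- function(B, attribution) {
  deg <- degree_split(B, attribution)
  H <- shannon_diversity(attr(attribution, "volumes"))
  idx <- match(deg$physician_id, attribution$physician_id)
  data.frame(deg,
             betweenness = as.numeric(net_betweenness(B)),
             H = as.numeric(H[deg$physician_id]),
             n_sites = attribution$n_sites[idx],
             n_nonprimary = attribution$n_nonprimary[idx],
             primary_hospital_id = attribution$primary_hospital_id[idx],
             stringsAsFactors = FALSE)
}

#' Threshold robustness sweep over shared-patient cutoffs
#'
#' Re-binarizes the weighted network at each cutoff, recomputes per-hospital
#' subnetwork densities, and compares each cutoff's density distribution to
#' the baseline (first) cutoff with a two-sided Wilcoxon rank-sum test.
#'
#' @param A a [project_shared_patients()] network.
#' @param attribution an [attribute_physicians()] table.
#' @param cutoffs nonnegative thresholds; default c(1, 10, 50, 100, 500,
#'   1000).
#' @param mode threshold comparison mode passed to [binarize()].
#' @return data.frame with one row per cutoff: cutoff, n_edges,
#'   mean/median/sd subnetwork density, and p_vs_baseline; the per-cutoff
#'   density vectors are attached as attribute `"densities"`.
#' @export
threshold_sweep <- function(A, attribution,
                            cutoffs = c(1, 10, 50, 100, 500, 1000),
                            mode = "strict") {
  if (length(cutoffs) == 0L)
    stopf("configuration error: empty cutoff list")
  if (any(cutoffs < 0))
    stopf("configuration error: cutoffs must be nonnegative")
  dens_list <- vector("list", length(cutoffs))
  rows <- vector("list", length(cutoffs))
  for (k in seq_along(cutoffs)) {
    B <- binarize(A, a_low = cutoffs[k], mode = mode)
    sd_k <- subnetwork_density(B, attribution)
    d <- sd_k$per_hospital$density
    d <- d[!is.na(d)]
    dens_list[[k]] <- d
    rows[[k]] <- data.frame(cutoff = cutoffs[k],
                            n_edges = length(B$edges@x) / 2,
                            mean_density = mean(d),
                            median_density = median(d),
                            sd_density = sd(d))
  }
  out <- do.call(rbind, rows)
  out$p_vs_baseline <- vapply(seq_along(cutoffs), function(k) {
    if (k == 1L) return(NA_real_)
    x <- dens_list[[1]]; y <- dens_list[[k]]
    if (length(x) < 1 || length(y) < 1) return(NA_real_)
    if (identical(x, y)) return(1)
    suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
  }, numeric(1))
  attr(out, "densities") <- setNames(dens_list, cutoffs)
  out
}
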