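# Construction of the shared-patient physician network and the
# shared-physician hospital network from billing records.

BILLING_COLS <- c("physician_id", "patient_id", "hospital_id", "date")

#' Read billing records from a delimited file
#'
#' Expects a UTF-8 delimited file with a header row and columns
#' physician_id, patient_id, hospital_id, date (ISO-8601). Rows with dates
#' outside the window are excluded.
#'
#' @param path file path.
#' @param window optional two-element date window (start, end), inclusive.
#' @return data.frame of billing records with `date` parsed to Date.
#' @export
read_billing <- function(path, window = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(BILLING_COLS, names(raw))
  if (length(missing_cols))
    stopf("schema error: missing column(s) %s",
          paste(missing_cols, collapse = ", "))
  raw <- raw[BILLING_COLS]
  if (nrow(raw) == 0L) {
    raw$date <- as.Date(character(0))
    return(raw)
  }
  if (any(!nzchar(raw$physician_id)) || any(!nzchar(raw$patient_id)) ||
      any(!nzchar(raw$hospital_id)))
    stopf("schema error: empty identifier(s) present")
  d <- as.Date(raw$date, format = "%Y-%m-%d")
  bad <- which(is.na(d))
  if (length(bad))
    stopf("unparseable date at line %s (value %s)",
          paste(bad[seq_len(min(5, length(bad)))] + 1L, collapse = ", "),
          raw$date[bad[1]])
  raw$date <- d
  records <- filter_window(raw, window)
  message(sprintf("read_billing: retained %d of %d rows", nrow(records),
                  nrow(raw)))
  records
}

filter_window <- function(records, window) {
  if (is.null(window)) return(records)
  w <- as_date_window(window)
  records[records$date >= w[1] & records$date <= w[2], , drop = FALSE]
}

#' Build the physician-by-patient encounter matrix
#'
#' Tallies z[i, k], the number of billed encounters physician i had with
#' patient k. Physicians and patients are ordered lexicographically by
#' identifier so outputs are reproducible.
#'
#' @param records billing data.frame (physician_id, patient_id, ...).
#' @return object of class `encounter_matrix`: list with `physicians`,
#'   `patients`, and sparse integer `counts`.
#' @export
build_encounter_matrix <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    out <- list(physicians = character(0), patients = character(0),
                counts = Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                              x = numeric(0), dims = c(0, 0)),
                empty = TRUE)
    class(out) <- "encounter_matrix"
    warning("build_encounter_matrix: empty input; returning empty matrix")
    return(out)
  }
  phys <- sort(unique(records$physician_id))
  pats <- sort(unique(records$patient_id))
  counts <- Matrix::sparseMatrix(
    i = match(records$physician_id, phys),
    j = match(records$patient_id, pats),
    x = 1, dims = c(length(phys), length(pats)),
    dimnames = list(phys, pats))
  out <- list(physicians = phys, patients = pats, counts = counts,
              empty = FALSE)
  class(out) <- "encounter_matrix"
  out
}

#' @export
print.encounter_matrix <- function(x, ...) {
  cat(sprintf("Encounter matrix: %d physicians x %d patients, %g encounters\n",
              length(x$physicians), length(x$patients), sum(x$counts)))
  invisible(x)
}

# coerce any sparse symmetric/triangular result to general numeric sparse
as_general_sparse <- function(M) {
  as(as(as(M, "CsparseMatrix"), "generalMatrix"), "dMatrix")
}

#' Project the encounter matrix to the shared-patient physician network
#'
#' Under the `shared-count` scheme the edge weight a[i, j] is the number of
#' patients seen by both physicians i and j (each shared patient counts
#' once, regardless of encounter multiplicity). Under the `geometric-mean`
#' scheme the weight is the sum over shared patients of
#' sqrt(z[i, k] * z[j, k]).
#'
#' @param Z an [build_encounter_matrix()] result.
#' @param scheme `"shared-count"` (default) or `"geometric-mean"`.
#' @return object of class `shared_patient_network`: list with
#'   `physicians`, symmetric sparse `weights` with zero diagonal, `scheme`.
#' @export
project_shared_patients <- function(Z, scheme = c("shared-count",
                                                  "geometric-mean")) {
  scheme <- match.arg(scheme)
  if (!inherits(Z, "encounter_matrix"))
    stopf("'Z' must be an encounter_matrix")
  M <- Z$counts
  W <- if (scheme == "shared-count") {
    P <- M; P@x[] <- 1
    Matrix::tcrossprod(P)
  } else {
    S <- M; S@x <- sqrt(S@x)
    Matrix::tcrossprod(S)
  }
  W <- as_general_sparse(W)
  Matrix::diag(W) <- 0
  W <- Matrix::drop0(W)
  out <- list(physicians = Z$physicians, weights = W, scheme = scheme)
  class(out) <- "shared_patient_network"
  out
}

#' @export
print.shared_patient_network <- function(x, ...) {
  nnz <- length(x$weights@x)
  cat(sprintf("Shared-patient network (%s): %d physicians, %d weighted edges\n",
              x$scheme, length(x$physicians), nnz / 2))
  invisible(x)
}

#' Binarize a weighted shared-patient network
#'
#' Applies the threshold rule b[i, j] = I(a[i, j] > a_low) (strict mode, the
#' default) or b[i, j] = I(a[i, j] >= a_low) (inclusive mode, matching a
#' "minimum shared patients" reading of the threshold). With a_low = 0 the
#' strict rule keeps any patient-sharing tie.
#'
#' @param A a [project_shared_patients()] network.
#' @param a_low nonnegative threshold.
#' @param mode `"strict"` or `"inclusive"`.
#' @return object of class `binary_network`: list with `physicians`, sparse
#'   0/1 `edges` (zero diagonal), `threshold`, `mode`.
#' @export
binarize <- function(A, a_low = 0, mode = c("strict", "inclusive")) {
  mode <- match.arg(mode)
  if (!inherits(A, "shared_patient_network"))
    stopf("'A' must be a shared_patient_network")
  if (!is.numeric(a_low) || length(a_low) != 1L || is.na(a_low) || a_low < 0)
    stopf("configuration error: 'a_low' must be a nonnegative number")
  W <- A$weights
  n <- length(A$physicians)
  if (mode == "strict" || a_low > 0) {
    keep <- if (mode == "strict") W@x > a_low else W@x >= a_low
    E <- W
    E@x[!keep] <- 0
    E@x[keep] <- 1
    E <- Matrix::drop0(E)
  } else {
    # inclusive threshold of 0 admits every pair, sharing or not
    E <- as_general_sparse(Matrix::Matrix(1, n, n,
                                          dimnames = dimnames(W)) -
                             Matrix::Diagonal(n))
  }
  out <- list(physicians = A$physicians, edges = E, threshold = a_low,
              mode = mode)
  class(out) <- "binary_network"
  out
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf(
    "Binary physician network: %d physicians, %d edges (a_low = %g, %s)\n",
    length(x$physicians), length(x$edges@x) / 2, x$threshold, x$mode))
  invisible(x)
}

#' Attribute physicians to hospitals by billing volume
#'
#' Tallies each physician's encounter volume per hospital, attributes the
#' primary hospital as the one with the largest volume (ties broken by the
#' lexicographically smallest hospital id), and counts billing sites.
#'
#' @param records billing data.frame.
#' @return data.frame of class `physician_attribution` with columns
#'   physician_id, primary_hospital_id, total_encounters, n_sites,
#'   n_nonprimary (ordered lexicographically by physician); the full
#'   physician-by-hospital volume matrix is attached as attribute
#'   `"volumes"`.
#' @export
attribute_physicians <- function(records) {
  if (is.null(records) || nrow(records) == 0L)
    stopf("attribute_physicians: no billing records")
  phys <- sort(unique(records$physician_id))
  hosp <- sort(unique(records$hospital_id))
  V <- matrix(0, length(phys), length(hosp), dimnames = list(phys, hosp))
  tab <- table(factor(records$physician_id, levels = phys),
               factor(records$hospital_id, levels = hosp))
  V[] <- as.numeric(tab)
  primary <- apply(V, 1L, function(v) {
    cand <- hosp[v == max(v)]
    sort(cand)[1]
  })
  out <- data.frame(physician_id = phys,
                    primary_hospital_id = unname(primary),
                    total_encounters = unname(rowSums(V)),
                    n_sites = unname(rowSums(V > 0)),
                    stringsAsFactors = FALSE)
  out$n_nonprimary <- out$n_sites - 1L
  attr(out, "volumes") <- V
  class(out) <- c("physician_attribution", "data.frame")
  out
}

#' Build the shared-physician hospital network
#'
#' Hospitals are nodes; the edge weight between two hospitals is the number
#' of distinct physicians who billed at both within the window.
#'
#' @param records billing data.frame.
#' @param window optional two-element date window.
#' @return object of class `hospital_network`: list with `hospitals`,
#'   symmetric integer `edges` matrix (zero diagonal), `window`.
#' @export
build_hospital_network <- function(records, window = NULL) {
  if (!is.null(window)) window <- as_date_window(window)
  records <- filter_window(records, window)
  if (nrow(records) == 0L)
    stopf("build_hospital_network: no records in window")
  pairs <- unique(records[c("physician_id", "hospital_id")])
  phys <- sort(unique(pairs$physician_id))
  hosp <- sort(unique(pairs$hospital_id))
  M <- matrix(0, length(phys), length(hosp), dimnames = list(phys, hosp))
  M[cbind(match(pairs$physician_id, phys),
          match(pairs$hospital_id, hosp))] <- 1
  E <- crossprod(M)
  diag(E) <- 0
  out <- list(hospitals = hosp, edges = E, window = window)
  class(out) <- "hospital_network"
  out
}

#' @export
print.hospital_network <- function(x, ...) {
  cat(sprintf("Hospital network: %d hospitals, %d edges\n",
              length(x$hospitals), sum(x$edges > 0) / 2))
  invisible(x)
}

#' Create a shared-patient network from a weight matrix
#'
#' Wraps an existing symmetric nonnegative weight matrix (zero diagonal) as
#' a `shared_patient_network`, e.g. for re-thresholding experiments.
#'
#' @param weights symmetric nonnegative matrix with zero diagonal; row
#'   names are used as physician ids (defaults to p1, p2, ...).
#' @param scheme weighting scheme label.
#' @return a `shared_patient_network`.
#' @export
as_shared_patient_network <- function(weights, scheme = "shared-count") {
  W <- as_general_sparse(Matrix::Matrix(weights, sparse = TRUE))
  if (nrow(W) != ncol(W) || !Matrix::isSymmetric(W))
    stopf("as_shared_patient_network: weights must be symmetric")
  if (any(Matrix::diag(W) != 0)) stopf("weights must have a zero diagonal")
  if (any(W@x < 0)) stopf("weights must be nonnegative")
  if (is.null(rownames(W)))
    dimnames(W) <- rep(list(paste0("p", seq_len(nrow(W)))), 2)
  out <- list(physicians = rownames(W), weights = W, scheme = scheme)
  class(out) <- "shared_patient_network"
  out
}

#' Create a binary network from a 0/1 adjacency matrix
#'
#' @param adjacency symmetric 0/1 matrix with zero diagonal; row names are
#'   used as physician ids (defaults to p1, p2, ...).
#' @param threshold threshold label to record.
#' @param mode comparison-mode label to record.
#' @return a `binary_network`.
#' @export
as_binary_network <- function(adjacency, threshold = 0, mode = "strict") {
  net <- as_shared_patient_network(adjacency)
  if (!all(net$weights@x %in% c(0, 1)))
    stopf("as_binary_network: entries must be 0/1")
  out <- list(physicians = net$physicians,
              edges = Matrix::drop0(net$weights),
              threshold = threshold, mode = mode)
  class(out) <- "binary_network"
  out
}

#' Convert a network object to an igraph graph
#'
#' @param x a `binary_network`, `shared_patient_network`, or
#'   `hospital_network`.
#' @return an undirected igraph graph (weighted for weighted sources).
#' @export
as_igraph <- function(x) {
  if (inherits(x, "binary_network")) {
    igraph::graph_from_adjacency_matrix(x$edges, mode = "undirected",
                                        diag = FALSE)
  } else if (inherits(x, "shared_patient_network")) {
    igraph::graph_from_adjacency_matrix(x$weights, mode = "undirected",
                                        weighted = TRUE, diag = FALSE)
  } else if (inherits(x, "hospital_network")) {
    igraph::graph_from_adjacency_matrix(x$edges, mode = "undirected",
                                        weighted = TRUE, diag = FALSE)
  } else stopf("cannot convert object of class %s", class(x)[1])
}

network_matrix <- function(x) {
  if (inherits(x, "binary_network")) x$edges
  else if (inherits(x, "shared_patient_network")) x$weights
  else if (inherits(x, "hospital_network")) x$edges
  else stopf("not a network object")
}

#' Write a network as a three-column edge list
#'
#' Writes `source,target,weight` (UTF-8, header row), one row per
#' undirected edge.
#'
#' @param x a network object.
#' @param path output file.
#' @return invisibly, the number of edges written.
#' @export
write_edge_list <- function(x, path) {
  M <- network_matrix(x)
  M <- as_general_sparse(Matrix::Matrix(M, sparse = TRUE))
  tr <- Matrix::summary(M)
  tr <- tr[tr$i < tr$j, , drop = FALSE]
  ids <- rownames(M)
  df <- data.frame(source = ids[tr$i], target = ids[tr$j], weight = tr$x)
  df <- df[order(df$source, df$target), , drop = FALSE]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(nrow(df))
}

#' Write a network in GraphML format
#'
#' @param x a network object.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_graphml <- function(x, path) {
  igraph::write_graph(as_igraph(x), path, format = "graphml")
  invisible(path)
}
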