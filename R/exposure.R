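# Within/across-hospital decomposition of the physician network,
# row-stochastic weight matrices, and step-masked peer-participation
# exposures.

#' Decompose a binary network into within- and across-hospital parts
#'
#' Splits the adjacency matrix by whether two physicians share the same
#' primary billing hospital. With physicians ordered by primary hospital,
#' the within part is block diagonal and the across part has zero blocks on
#' its diagonal; elementwise they sum back to the original network.
#'
#' @param B a [binarize()] network.
#' @param attribution an [attribute_physicians()] table covering every
#'   physician in `B`.
#' @return object of class `network_decomposition`: list with sparse
#'   `B_wi`, `B_ac`, the aligned `primary` hospital vector, and
#'   `physicians`.
#' @export
decompose_network <- function(B, attribution) {
  stopifnot(inherits(B, "binary_network"))
  missing_phys <- setdiff(B$physicians, attribution$physician_id)
  if (length(missing_phys))
    stopf("decompose_network: unattributed physician(s): %s",
          paste(head(missing_phys, 5), collapse = ", "))
  prim <- attribution$primary_hospital_id[
    match(B$physicians, attribution$physician_id)]
  n <- length(B$physicians)
  E <- as_general_sparse(B$edges)
  tr <- Matrix::summary(E)
  same <- prim[tr$i] == prim[tr$j]
  mk <- function(keep) {
    Matrix::sparseMatrix(i = tr$i[keep], j = tr$j[keep], x = tr$x[keep],
                         dims = c(n, n),
                         dimnames = list(B$physicians, B$physicians))
  }
  out <- list(B_wi = mk(same), B_ac = mk(!same), primary = prim,
              physicians = B$physicians)
  class(out) <- "network_decomposition"
  out
}

#' Row-normalize a nonnegative matrix to a row-stochastic weight matrix
#'
#' Divides each row by its sum; rows with zero sum are kept all-zero and
#' flagged rather than producing NaN.
#'
#' @param Bx a nonnegative (sparse) matrix.
#' @return object of class `weight_matrix`: list with `W` and logical
#'   `zero_row` flags.
#' @export
row_normalize <- function(Bx) {
  if (inherits(Bx, "network_decomposition"))
    stopf("row_normalize: pass one component (B_wi or B_ac), not the decomposition")
  Bx <- as_general_sparse(Matrix::Matrix(Bx, sparse = TRUE))
  if (any(Bx@x < 0)) stopf("row_normalize: matrix must be nonnegative")
  rs <- Matrix::rowSums(Bx)
  zero <- rs == 0
  inv <- ifelse(zero, 0, 1 / rs)
  W <- Matrix::Diagonal(x = inv) %*% Bx
  W <- as_general_sparse(W)
  dimnames(W) <- dimnames(Bx)
  out <- list(W = W, zero_row = setNames(zero, rownames(Bx)))
  class(out) <- "weight_matrix"
  out
}

check_outcome <- function(y, ids) {
  if (!is.null(names(y))) y <- y[ids]
  if (length(y) != length(ids) || any(is.na(y)))
    stopf("structural error: outcome must align with the %d network physicians",
          length(ids))
  if (!all(y %in% c(0, 1)))
    stopf("structural error: outcome must be binary 0/1")
  as.numeric(y)
}

#' Within-hospital peer-participation exposure
#'
#' The percentage (0-100) of a physician's within-hospital network peers
#' who participated: 100 * [W_wi Y]_i. Physicians with no within peers
#' (flagged rows of the weight matrix) get exposure 0 and a flag.
#'
#' @param W_wi a [row_normalize()]d within-hospital weight matrix.
#' @param y binary participation outcomes, named by physician_id or aligned
#'   to the matrix rows.
#' @return list with `exposure` (named percent vector) and `flagged`.
#' @export
within_exposure <- function(W_wi, y) {
  stopifnot(inherits(W_wi, "weight_matrix"))
  ids <- rownames(W_wi$W)
  yv <- check_outcome(y, ids)
  expo <- 100 * as.numeric(W_wi$W %*% yv)
  list(exposure = setNames(expo, ids), flagged = W_wi$zero_row)
}

#' Step-masked across-hospital peer-participation exposure
#'
#' Restricts each physician's across-hospital peer set to physicians whose
#' primary hospital was randomized at the same trial step or earlier (a
#' guard against reverse causality), *then* row-normalizes, so weights are
#' a proper average over eligible peers, and computes the participation
#' proportion [W Y]_i on the 0-1 scale. Physicians with no eligible peers
#' are flagged with exposure 0.
#'
#' @param B_ac the across-hospital binary matrix from
#'   [decompose_network()].
#' @param y binary outcomes, named or aligned.
#' @param steps named vector mapping hospital_id to trial step.
#' @param attribution an [attribute_physicians()] table.
#' @return object of class `across_exposure`: list with `exposure` (named
#'   proportion vector), `flagged`, the masked weight matrix `W`, and the
#'   masked binary matrix `B_masked`.
#' @export
across_exposure <- function(B_ac, y, steps, attribution) {
  ids <- rownames(B_ac)
  prim <- attribution$primary_hospital_id[
    match(ids, attribution$physician_id)]
  if (anyNA(prim))
    stopf("across_exposure: unattributed physician(s)")
  st <- steps[prim]
  if (anyNA(st))
    stopf("across_exposure: hospital(s) without a step assignment: %s",
          paste(head(unique(prim[is.na(st)]), 5), collapse = ", "))
  E <- as_general_sparse(Matrix::Matrix(B_ac, sparse = TRUE))
  tr <- Matrix::summary(E)
  keep <- st[tr$j] <= st[tr$i]
  masked <- Matrix::sparseMatrix(i = tr$i[keep], j = tr$j[keep],
                                 x = tr$x[keep],
                                 dims = dim(E), dimnames = dimnames(E))
  Wm <- row_normalize(masked)
  yv <- check_outcome(y, ids)
  expo <- as.numeric(Wm$W %*% yv)
  out <- list(exposure = setNames(expo, ids), flagged = Wm$zero_row,
              W = Wm$W, B_masked = masked, step = setNames(st, ids))
  class(out) <- "across_exposure"
  out
}

#' Transform the across-hospital exposure for modelling
#'
#' The default `"ln1p-percent"` transform maps a proportion p to
#' ln(1 + 100 p): a natural-log transform of the percent-scale exposure
#' that is defined (and equal to 0) at p = 0 and monotone increasing.
#' `"identity"` keeps the raw proportion; `"ln-offset"` computes
#' ln(p + eps).
#'
#' @param wy_ac proportions in \[0, 1\].
#' @param method one of `"ln1p-percent"`, `"identity"`, `"ln-offset"`.
#' @param eps offset for `"ln-offset"`.
#' @return transformed numeric vector.
#' @export
transform_across <- function(wy_ac, method = c("ln1p-percent", "identity",
                                               "ln-offset"), eps = 0.01) {
  method <- match.arg(method)
  switch(method,
         "ln1p-percent" = log1p(100 * wy_ac),
         "identity" = wy_ac,
         "ln-offset" = log(wy_ac + eps))
}

#' Per-physician exposure table
#'
#' Runs the full exposure computation — decomposition, row normalization,
#' within exposure (percent), step-masked across exposure (proportion plus
#' transform) — and joins the Shannon diversity and site counts.
#'
#' @param B a [binarize()] network.
#' @param attribution an [attribute_physicians()] table. When its volume
#'   matrix attribute is absent the `H` column is `NA`.
#' @param y binary outcomes, named by physician_id or aligned.
#' @param steps named hospital step vector.
#' @param transform across-exposure transform; see [transform_across()].
#' @return data.frame keyed by physician_id with within/across degree,
#'   wy_wi (0-100), wy_ac (0-1), wy_ac_trans, undefined-exposure flags, H,
#'   n_nonprimary, primary hospital and step.
#' @export
exposure_table <- function(B, attribution, y, steps,
                           transform = "ln1p-percent") {
  dec <- decompose_network(B, attribution)
  Wwi <- row_normalize(dec$B_wi)
  wi <- within_exposure(Wwi, y)
  ac <- across_exposure(dec$B_ac, y, steps, attribution)
  vol <- attr(attribution, "volumes")
  H <- if (is.null(vol)) {
    stats::setNames(rep(NA_real_, nrow(attribution)),
                    attribution$physician_id)
  } else {
    shannon_diversity(vol)
  }
  idx <- match(B$physicians, attribution$physician_id)
  data.frame(physician_id = B$physicians,
             primary_hospital_id = dec$primary,
             step = as.integer(ac$step),
             within_degree = as.integer(round(Matrix::rowSums(dec$B_wi))),
             across_degree = as.integer(round(Matrix::rowSums(dec$B_ac))),
             wy_wi = as.numeric(wi$exposure),
             wy_wi_flagged = as.logical(wi$flagged),
             wy_ac = as.numeric(ac$exposure),
             wy_ac_flagged = as.logical(ac$flagged),
             wy_ac_trans = transform_across(as.numeric(ac$exposure),
                                            method = transform),
             H = as.numeric(H[B$physicians]),
             n_sites = attribution$n_sites[idx],
             n_nonprimary = attribution$n_nonprimary[idx],
             stringsAsFactors = FALSE)
}
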