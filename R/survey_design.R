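#' Stratified cluster survey design
#'
#' Binds microdata to its complex-sample design: stratum and primary sampling
#' unit (PSU) identifiers and expansion weights. All design-based estimators
#' in the package (weighted proportions, survey-weighted logistic models,
#' goodness-of-fit, margins) draw their variance structure from this object.
#' Design degrees of freedom are the conventional (number of PSUs) minus
#' (number of strata).
#'
#' Subsetting with [subset_svy_design()] keeps the full PSU frame of the
#' parent design, so domain (subpopulation) estimates use the correct
#' full-design variance rather than treating the subset as a new sample.
#'
#' @param data Microdata tibble.
#' @param strata,psu,weight Column names of the stratum id, PSU id and
#'   expansion weight.
#' @param single_psu What to do with strata containing a single PSU:
#'   `"error"` (default; the between-PSU variance is undefined) or
#'   `"collapse"` (merge each singleton stratum with the preceding stratum,
#'   a pragmatic rule for real data).
#' @return An object of class `svy_design`.
#' @export
svy_design <- function(data, strata = "stratum_id", psu = "psu_id",
                       weight = "weight", single_psu = c("error", "collapse")) {
  single_psu <- match.arg(single_psu)
  for (cl in c(strata, psu, weight)) {
    if (!cl %in% names(data)) abort_config(sprintf("design column '%s' not found", cl))
  }
  w <- data[[weight]]
  if (any(is.na(w)) || any(w <= 0)) abort_validation("weights must be strictly positive")

  st <- as.character(data[[strata]])
  ps <- paste(st, as.character(data[[psu]]), sep = "\r")
  frame <- tibble::tibble(stratum = st, psu_key = ps)
  frame <- frame[!duplicated(frame$psu_key), , drop = FALSE]
  per_stratum <- table(frame$stratum)
  if (any(per_stratum < 2)) {
    if (single_psu == "error") {
      abort_config(sprintf(
        "stratum/strata with a single PSU (%s); variance undefined. Use single_psu = 'collapse' to merge.",
        paste(names(per_stratum)[per_stratum < 2], collapse = ", ")))
    }
    # collapse each singleton stratum into the preceding stratum (cyclic)
    lev <- sort(unique(st), method = "radix")
    remap <- stats::setNames(lev, lev)
    for (i in seq_along(lev)) {
      if (per_stratum[[lev[i]]] < 2) {
        target <- lev[if (i > 1) i - 1 else length(lev)]
        remap[lev[i]] <- remap[target]
      }
    }
    st <- unname(remap[st])
    data[[strata]] <- st
    ps <- paste(st, as.character(data[[psu]]), sep = "\r")
    frame <- tibble::tibble(stratum = st, psu_key = ps)
    frame <- frame[!duplicated(frame$psu_key), , drop = FALSE]
  }

  structure(list(
    variables = tibble::as_tibble(data),
    strata_col = strata, psu_col = psu, weight_col = weight,
    psu_frame = frame,
    n_strata = length(unique(frame$stratum)),
    n_psu = nrow(frame),
    df = nrow(frame) - length(unique(frame$stratum))
  ), class = "svy_design")
}

#' @export
print.svy_design <- function(x, ...) {
  cat(sprintf("Stratified cluster design: %d records, %d strata, %d PSUs (df = %d)\n",
              nrow(x$variables), x$n_strata, x$n_psu, x$df))
  invisible(x)
}

#' Subset a survey design, keeping the full variance structure
#'
#' @param design A [svy_design()] object.
#' @param subset Logical vector (or expression result) selecting rows.
#' @return A `svy_design` whose `variables` are subset but whose PSU frame
#'   and degrees of freedom are inherited from the parent design.
#' @export
subset_svy_design <- function(design, subset) {
  stopifnot(inherits(design, "svy_design"))
  out <- design
  out$variables <- design$variables[subset, , drop = FALSE]
  out
}

design_psu_keys <- function(design, data = design$variables) {
  paste(as.character(data[[design$strata_col]]),
        as.character(data[[design$psu_col]]), sep = "\r")
}

# Stratified between-PSU (Taylor linearization) covariance of a total.
# z: n x k matrix of per-record linearized contributions (weights included).
# Centering and the n_h/(n_h - 1) factor use the FULL PSU frame: PSUs of the
# frame absent from the rows contribute zero totals (domain estimation).
taylor_linearized_vcov <- function(z, psu_keys, psu_frame) {
  z <- as.matrix(z)
  k <- ncol(z)
  tot <- matrix(0, nrow(psu_frame), k)
  rownames(tot) <- psu_frame$psu_key
  if (nrow(z) > 0) {
    got <- rowsum(z, psu_keys, reorder = FALSE)
    miss <- setdiff(rownames(got), psu_frame$psu_key)
    if (length(miss) > 0) {
      abort_validation("records reference PSUs outside the design frame")
    }
    tot[rownames(got), ] <- got
  }
  V <- matrix(0, k, k)
  for (h in unique(psu_frame$stratum)) {
    rows <- tot[psu_frame$stratum == h, , drop = FALSE]
    n_h <- nrow(rows)
    if (n_h < 2) next
    cen <- sweep(rows, 2, colMeans(rows))
    V <- V + n_h / (n_h - 1) * crossprod(cen)
  }
  V
}
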