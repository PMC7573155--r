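# broom-style tidiers ---------------------------------------------------------

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted factor model
#'
#' One row per retained item and factor, with the rotated loading and the
#' Anderson-Rubin score weight.
#'
#' @param x A `factor_model`.
#' @param ... Unused.
#' @return A tibble: `item`, `factor`, `loading`, `score_weight`,
#'   `communality`, `msa`.
#' @method tidy factor_model
#' @export
tidy.factor_model <- function(x, ...) {
  lam <- tibble::as_tibble(x$loadings)
  lam$item <- x$retained_items
  out <- tidyr::pivot_longer(lam, -"item", names_to = "factor",
                             values_to = "loading")
  w <- tibble::as_tibble(x$score_weights)
  w$item <- x$retained_items
  w <- tidyr::pivot_longer(w, -"item", names_to = "factor",
                           values_to = "score_weight")
  out <- dplyr::left_join(out, w, by = c("item", "factor"))
  out$communality <- x$communalities[match(out$item, x$retained_items)]
  out$msa <- unname(x$msa[match(out$item, x$retained_items)])
  out
}

#' @rdname tidy.factor_model
#' @method glance factor_model
#' @export
glance.factor_model <- function(x, ...) {
  tibble::tibble(
    n_items = length(x$all_items),
    n_retained = length(x$retained_items),
    n_dropped = nrow(x$dropped_items),
    n_factors = x$n_factors,
    kmo = x$kmo,
    variance_explained = x$variance_explained,
    converged = x$converged
  )
}

#' Tidy an NBS result
#'
#' One row per suprathreshold component with extent, intensity and their
#' FWER p-values.
#'
#' @param x An `nbs_result`.
#' @param ... Unused.
#' @return The component tibble.
#' @method tidy nbs_result
#' @export
tidy.nbs_result <- function(x, ...) x$component_table

#' @rdname tidy.nbs_result
#' @method glance nbs_result
#' @export
glance.nbs_result <- function(x, ...) {
  tbl <- x$component_table
  tibble::tibble(
    direction = x$direction, df = x$df, t_thresh = x$t_thresh,
    n_components = length(x$components),
    min_p_extent = if (nrow(tbl)) min(tbl$p_extent) else NA_real_,
    min_p_intensity = if (nrow(tbl)) min(tbl$p_intensity) else NA_real_,
    n_significant = if (nrow(tbl)) sum(tbl$p_extent <= x$alpha) else 0L,
    n_perm = x$n_perm, alpha = x$alpha
  )
}

#' Tidy a cross-validation result
#'
#' Pooled held-out predictions (LOOCV) or per-redraw correlations (3-fold).
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) {
  if (x$scheme == "loocv") x$predictions else x$per_redraw
}

#' @rdname tidy.cv_result
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    scheme = x$scheme, strategy = x$strategy, circular = x$circular,
    with_covariates = x$with_covariates, signed = x$signed,
    r_pooled = x$r_pooled %||% NA_real_, r_median = x$r_median,
    n_flagged = x$n_flagged
  )
}
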