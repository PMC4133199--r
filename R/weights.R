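#' Weight context: the geometric quantities a contour weight may use
#'
#' For one contributing atlas contour file versus the case under
#' prediction: `v_psa` the contributing contour's volume (cm^3, required),
#' `v_p` the predicted case's contour volume, `v_o` their overlap volume,
#' and `d` the distance between their centroids (mm). `v_p`, `v_o`, `d`
#' may be absent for the variants that do not depend on the predicted case
#' (ids 1 and 2).
#'
#' @param v_psa contributing contour volume, cm^3 (> 0).
#' @param v_p predicted contour volume, cm^3, or NULL.
#' @param v_o overlap volume, cm^3, or NULL.
#' @param d centroid distance, mm, or NULL.
#' @return object of class `weight_context`.
#' @export
weight_context <- function(v_psa, v_p = NULL, v_o = NULL, d = NULL) {
  if (!is.numeric(v_psa) || length(v_psa) != 1 || !(v_psa > 0))
    stop("weight_context: v_psa must be a single positive volume")
  if (!is.null(v_p) && !(v_p > 0))
    stop("weight_context: v_p must be > 0 when present")
  if (!is.null(d) && d < 0)
    stop("weight_context: d must be >= 0")
  if (!is.null(v_o)) {
    hi <- min(v_psa, if (is.null(v_p)) Inf else v_p)
    if (v_o < 0 || v_o > hi + 1e-9)
      stop("weight_context: v_o must satisfy 0 <= v_o <= min(v_psa, v_p)")
  }
  structure(list(v_psa = v_psa, v_p = v_p, v_o = v_o, d = d),
            class = "weight_context")
}

# Registry of weight variants. Ids 1-8 are the built-in aggregation
# schemes; user-defined variants register under ids >= 9.
.weight_registry <- new.env(parent = emptyenv())

#' Register a weight variant
#'
#' @param id integer id; built-ins occupy 1..8, user variants must use >= 9.
#' @param fn function(ctx) -> nonnegative scalar weight.
#' @param needs_predicted_case does the formula use `v_p`/`v_o`/`d`? Such
#'   variants cannot be pre-computed or merged.
#' @param description short label.
#' @export
register_weight <- function(id, fn, needs_predicted_case = TRUE,
                            description = "") {
  id <- as.integer(id)
  if (is.na(id) || id < 9L)
    stop("register_weight: user-defined weight ids must be >= 9")
  stopifnot(is.function(fn))
  assign(as.character(id),
         list(id = id, fn = fn,
              needs_predicted_case = isTRUE(needs_predicted_case),
              description = description),
         envir = .weight_registry)
  invisible(id)
}

register_builtin <- function(id, fn, needs_predicted_case, description) {
  assign(as.character(as.integer(id)),
         list(id = as.integer(id), fn = fn,
              needs_predicted_case = needs_predicted_case,
              description = description),
         envir = .weight_registry)
}

#' Look up a weight variant's specification
#' @param id weight id.
#' @return list with `id`, `fn`, `needs_predicted_case`, `description`.
#' @export
weight_spec <- function(id) {
  key <- as.character(as.integer(id))
  if (!exists(key, envir = .weight_registry))
    stop(sprintf("unknown weight id %s", id))
  get(key, envir = .weight_registry)
}

# The eight built-in aggregation schemes. The published formula panel is
# not machine-readable; these expressions realize the stated behaviour of
# each variant: w1 plain averaging; w2 favours small (well-localized)
# contours and recurs as the 1/v_psa factor in w3 and w6-w8; w3, w4, w8
# reward overlap with the predicted contour; w5 rewards proximity of the
# centroids; w6 and w7 penalize the non-overlapping remainder of the
# contributing / predicted contour respectively. For identical contours
# (v_psa = v_p = v_o) w3 attains its maximum value 2.
local({
  register_builtin(1L, function(ctx) 1,
                   FALSE, "plain averaging (no weighting)")
  register_builtin(2L, function(ctx) 1 / ctx$v_psa,
                   FALSE, "favours small PSA contours")
  register_builtin(3L, function(ctx) ctx$v_o / ctx$v_psa + ctx$v_o / ctx$v_p,
                   TRUE, "overlap fractions of both contours")
  register_builtin(4L, function(ctx) ctx$v_o / ctx$v_p,
                   TRUE, "overlap fraction of the predicted contour")
  register_builtin(5L, function(ctx) 1 / (1 + ctx$d),
                   TRUE, "centroid proximity")
  register_builtin(6L, function(ctx)
    (1 / ctx$v_psa) * (1 - (ctx$v_psa - ctx$v_o) / ctx$v_psa),
    TRUE, "penalizes unoverlapped PSA remainder")
  register_builtin(7L, function(ctx)
    (1 / ctx$v_psa) * (1 - (ctx$v_p - ctx$v_o) / ctx$v_p),
    TRUE, "penalizes unoverlapped predicted remainder")
  register_builtin(8L, function(ctx) (1 / ctx$v_psa) * (ctx$v_o / ctx$v_p),
                   TRUE, "size-normalized overlap fraction")
})

#' Compute the weight of one contributing contour
#'
#' @param k weight id (1..8 built in, or a registered user id).
#' @param ctx a [weight_context()].
#' @return nonnegative scalar.
#' @examples
#' compute_weight(1, weight_context(10))            # 1
#' ctx <- weight_context(5, v_p = 5, v_o = 5, d = 0)
#' compute_weight(3, ctx)                           # 2: identical contours
#' @export
compute_weight <- function(k, ctx) {
  stopifnot(inherits(ctx, "weight_context"))
  spec <- weight_spec(k)
  if (spec$needs_predicted_case &&
      (is.null(ctx$v_p) || is.null(ctx$v_o) || is.null(ctx$d)))
    stop(sprintf(
      "compute_weight: weight %d needs the predicted case (v_p, v_o, d)",
      spec$id))
  w <- spec$fn(ctx)
  if (!is.finite(w) || w < 0)
    stop(sprintf("compute_weight: weight %d produced an invalid value", spec$id))
  w
}
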