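#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an annotation matrix into long form
#' @param x A `qa_annotation`.
#' @param ... Unused.
#' @return Tibble with `window`, `anchor_time`, `qid`, `answer`.
#' @export
tidy.qa_annotation <- function(x, ...) {
  tibble::tibble(
    window = rep(seq_len(nrow(x$values)), times = ncol(x$values)),
    anchor_time = rep(x$anchor_time, times = ncol(x$values)),
    qid = rep(x$qids, each = nrow(x$values)),
    answer = as.integer(x$values)
  )
}

#' Tidy a fitted encoding model
#' @param x A `qa_encoding`.
#' @param ... Unused.
#' @return Tibble with one row per (feature column, target): label columns,
#'   `target`, `weight` (standardized space), `alpha`.
#' @export
tidy.qa_encoding <- function(x, ...) {
  F_ <- nrow(x$weights); V <- ncol(x$weights)
  labs <- x$labels %||% tibble::tibble(qid = rownames(x$weights) %||%
                                         paste0("f", seq_len(F_)))
  out <- labs[rep(seq_len(F_), times = V), , drop = FALSE]
  out$target <- rep(seq_len(V), each = F_)
  out$weight <- as.numeric(x$weights)
  out$alpha <- rep(x$alpha, each = F_)
  tibble::as_tibble(out)
}

#' One-row summary of a fitted encoding model
#' @param x A `qa_encoding`.
#' @param ... Unused.
#' @return Tibble with `n_features`, `n_targets`, `mean_cv_r`, `median_alpha`,
#'   `n_degenerate`.
#' @export
glance.qa_encoding <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$weights),
    n_targets = ncol(x$weights),
    mean_cv_r = mean(x$cv_r),
    median_alpha = stats::median(x$alpha),
    n_degenerate = sum(x$degenerate)
  )
}

#' Tidy a stability-selection result
#' @param x A `qa_selection`.
#' @param ... Unused.
#' @return Tibble with `qid`, `frequency`, `mean_abs_weight`, `selected`.
#' @export
tidy.qa_selection <- function(x, ...) {
  tibble::tibble(
    qid = names(x$frequency),
    frequency = unname(x$frequency),
    mean_abs_weight = unname(x$mean_abs_weight[names(x$frequency)]),
    selected = names(x$frequency) %in% x$selected_qids
  )
}

#' One-row summary of a stability-selection result
#' @param x A `qa_selection`.
#' @param ... Unused.
#' @return Tibble with `n_questions`, `n_selected`, `threshold`, `B`, `frac`.
#' @export
glance.qa_selection <- function(x, ...) {
  tibble::tibble(
    n_questions = length(x$frequency),
    n_selected = length(x$selected_qids),
    threshold = x$threshold,
    B = x$B,
    frac = x$frac
  )
}

#' Tidy a score vector
#' @param x A `qa_scores`.
#' @param ... Unused.
#' @return Tibble with `target`, `r`, `valid`.
#' @export
tidy.qa_scores <- function(x, ...) {
  tibble::tibble(target = seq_along(x$r), r = x$r, valid = x$valid)
}

#' Tidy a lag-model set
#' @param x A `qa_lagmodels`.
#' @param ... Unused.
#' @return Tibble with `lag`, `electrode`, `r`.
#' @export
tidy.qa_lagmodels <- function(x, ...) {
  tibble::tibble(
    lag = rep(x$lags, times = ncol(x$scores)),
    electrode = rep(colnames(x$scores) %||% as.character(seq_len(ncol(x$scores))),
                    each = length(x$lags)),
    r = as.numeric(x$scores)
  )
}
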