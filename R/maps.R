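#' Per-question selectivity maps from an encoding model
#'
#' Collapses the FIR-delayed (and, for ECoG, multi-timescale) weights of a
#' fitted encoding model to one value per question and target by averaging
#' over each question's columns. Each row is a selectivity map: where that
#' question's theory explains responses.
#'
#' @param m A `qa_encoding` fitted on a labelled design.
#' @return A Q x V matrix with qids as row names.
#' @export
selectivity_maps <- function(m) {
  stopifnot(inherits(m, "qa_encoding"))
  if (is.null(m$labels)) stop("model was fit on an unlabelled design")
  qids <- unique(m$labels$qid)
  out <- t(vapply(qids, function(q) {
    colMeans(m$weights[m$labels$qid == q, , drop = FALSE])
  }, numeric(ncol(m$weights))))
  rownames(out) <- qids
  out
}

#' Best-predicted target mask
#'
#' Indices of the top `fraction` of targets by prediction score, the standard
#' mask for map-level comparisons (selectivity weights are only meaningful
#' where the model predicts). Boundary ties are broken by lower index.
#'
#' @param score A `qa_scores` or numeric score vector.
#' @param fraction Fraction of targets to keep, in `(0, 1]`.
#' @return Sorted integer index vector of length `ceiling(fraction * V)`.
#' @export
top_fraction_mask <- function(score, fraction) {
  r <- if (inherits(score, "qa_scores")) score$r else as.numeric(score)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  k <- ceiling(fraction * length(r))
  sort(order(-r, seq_along(r))[seq_len(k)])
}

#' Correlation between a selectivity map and a reference map
#'
#' Pearson correlation across targets between a weight map and a reference
#' vector (e.g. a meta-analysis map or a condition-average response),
#' optionally restricted to a mask of well-predicted targets. A constant
#' masked vector gives the sentinel 0 with attribute `valid = FALSE`.
#'
#' @param a Numeric weight map (length V).
#' @param b Numeric reference vector (length V).
#' @param mask Optional integer/logical mask with at least 3 targets.
#' @return Scalar correlation with attribute `valid`.
#' @export
map_correlation <- function(a, b, mask = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("maps have different lengths")
  if (!is.null(mask)) { a <- a[mask]; b <- b[mask] }
  if (length(a) < 3) stop("need at least 3 targets to correlate maps")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(structure(0, valid = FALSE))
  }
  structure(stats::cor(a, b), valid = TRUE)
}

#' Permutation test on a mean map correlation
#'
#' Tests whether the mean across questions of map correlations is greater
#' than zero. The null distribution is built by permuting the reference
#' map's values across targets independently for each question and
#' recomputing all correlations; this preserves the weight maps' spatial
#' statistics. The p-value uses the add-one rule
#' `p = (1 + #(null mean >= observed mean)) / (1 + n_perm)`, so its floor is
#' `1 / (1 + n_perm)`.
#'
#' @param weight_maps Q x V matrix of weight maps (rows = questions).
#' @param reference_maps Q x V matrix of reference maps, or a single length-V
#'   vector recycled across questions.
#' @param mask Optional target mask applied to every correlation.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return List with `p`, `observed_mean`, `observed` (per-question r),
#'   `null_means`.
#' @export
permutation_pvalue_mean <- function(weight_maps, reference_maps, mask = NULL,
                                    n_perm = 1000, seed = 1) {
  weight_maps <- rbind(weight_maps)
  if (is.null(dim(reference_maps))) {
    reference_maps <- matrix(reference_maps, nrow = nrow(weight_maps),
                             ncol = length(reference_maps), byrow = TRUE)
  }
  Q <- nrow(weight_maps)
  if (Q == 0) stop("no observed correlations: empty map set")
  if (n_perm < 100) stop("need n_perm >= 100")
  if (is.null(mask)) mask <- seq_len(ncol(weight_maps))
  Wm <- weight_maps[, mask, drop = FALSE]
  Rm <- reference_maps[, mask, drop = FALSE]
  observed <- vapply(seq_len(Q), function(q) as.numeric(map_correlation(Wm[q, ], Rm[q, ])),
                     numeric(1))
  obs_mean <- mean(observed)
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  n_t <- ncol(Wm)
  null_means <- vapply(seq_len(n_perm), function(b) {
    mean(vapply(seq_len(Q), function(q) {
      as.numeric(map_correlation(Wm[q, ], Rm[q, sample.int(n_t)]))
    }, numeric(1)))
  }, numeric(1))
  p <- (1 + sum(null_means >= obs_mean)) / (1 + n_perm)
  list(p = p, observed_mean = obs_mean, observed = observed, null_means = null_means)
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Returns the indices rejected by the standard step-up rule at level `q`:
#' with sorted p-values `p(1) <= ... <= p(m)`, reject hypotheses 1..k for the
#' largest `k` with `p(k) <= k * q / m` (the boundary is inclusive).
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param q False discovery rate level.
#' @return Integer vector of rejected indices (possibly empty).
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  pvals <- as.numeric(pvals)
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  which(stats::p.adjust(pvals, method = "BH") <= q)
}

#' Inter-subject consistency of selectivity maps
#'
#' For each held-out subject and question: project the other subjects' maps
#' to a common template, average them there, project the average back to the
#' held-out subject's space, and correlate with that subject's own map. The
#' alignment operators are user-supplied linear resamplers (matrices); use
#' identity operators when all subjects already share a space.
#'
#' @param maps_by_subject Named list of Q x V_s weight matrices (shared qid
#'   row names).
#' @param to_template Named list of V_template x V_s projection matrices
#'   (default: identity, requiring equal V_s).
#' @param from_template Named list of V_s x V_template back-projections
#'   (default: identity).
#' @return Tibble with columns `subject`, `qid`, `r`.
#' @export
intersubject_consistency <- function(maps_by_subject, to_template = NULL,
                                     from_template = NULL) {
  subjects <- names(maps_by_subject)
  if (length(subjects) < 2) stop("need at least 2 subjects")
  qid_sets <- lapply(maps_by_subject, rownames)
  shared <- Reduce(intersect, qid_sets)
  dropped <- setdiff(unique(unlist(qid_sets)), shared)
  if (length(dropped) > 0) {
    warning("qid(s) missing in some subject(s), skipped: ",
            paste(dropped, collapse = ", "))
  }
  proj <- function(ops, s, M) {
    if (is.null(ops)) return(M)
    op <- ops[[s]]
    t(op %*% t(M))
  }
  rows <- list()
  for (s in subjects) {
    others <- setdiff(subjects, s)
    templ <- lapply(others, function(o) {
      proj(to_template, o, maps_by_subject[[o]][shared, , drop = FALSE])
    })
    avg <- Reduce(`+`, templ) / length(templ)
    back <- proj(from_template, s, avg)
    own <- maps_by_subject[[s]][shared, , drop = FALSE]
    r <- vapply(shared, function(q) as.numeric(map_correlation(own[q, ], back[q, ])),
                numeric(1))
    rows[[s]] <- tibble::tibble(subject = s, qid = shared, r = unname(r))
  }
  dplyr::bind_rows(rows)
}

#' Condition-average responses for tagged stimulus segments
#'
#' Averages response rows over the stimulus segments tagged to each
#' question, after shifting every segment by a fixed hemodynamic offset
#' (default +2 samples, about 4 s at TR = 2 s) to compensate for the BOLD
#' lag. This is the measured-selectivity side of a condition-average
#' (generative causal testing style) comparison with fitted weight maps.
#'
#' @param Y Numeric T x V response matrix.
#' @param segments Data frame with columns `qid`, `start`, `end` (1-based
#'   inclusive row ranges); every qid needs at least one segment.
#' @param offset Hemodynamic shift in samples (default 2). Shifted rows
#'   beyond `T` are dropped.
#' @return A Q x V matrix of mean responses with qids as row names.
#' @export
condition_average_response <- function(Y, segments, offset = 2) {
  Y <- as.matrix(Y)
  stopifnot(all(c("qid", "start", "end") %in% names(segments)))
  if (nrow(segments) == 0) stop("no segments supplied")
  if (any(segments$end < segments$start)) stop("empty segment (end < start)")
  if (any(segments$start < 1 | segments$end > nrow(Y))) {
    stop("segment range outside the response matrix")
  }
  qids <- unique(segments$qid)
  out <- matrix(NA_real_, nrow = length(qids), ncol = ncol(Y),
                dimnames = list(qids, colnames(Y)))
  for (q in qids) {
    seg <- segments[segments$qid == q, , drop = FALSE]
    rows <- unlist(lapply(seq_len(nrow(seg)), function(i) {
      seq(seg$start[i], seg$end[i]) + offset
    }))
    rows <- rows[rows >= 1 & rows <= nrow(Y)]
    if (length(rows) == 0) stop("segment for qid '", q, "' empty after hemodynamic shift")
    out[q, ] <- colMeans(Y[rows, , drop = FALSE])
  }
  out
}

#' Write / read a flat selectivity map as TSV
#' @param values Named or plain numeric vector (one value per target).
#' @param path File path.
#' @return `write_map_tsv`: `path` invisibly; `read_map_tsv`: numeric vector.
#' @export
write_map_tsv <- function(values, path) {
  ids <- names(values) %||% as.character(seq_along(values))
  readr::write_tsv(tibble::tibble(target_id = ids, value = as.numeric(values)), path)
  invisible(path)
}

#' @rdname write_map_tsv
#' @export
read_map_tsv <- function(path) {
  tab <- readr::read_tsv(path, col_types = "cd", progress = FALSE)
  stats::setNames(tab$value, tab$target_id)
}
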