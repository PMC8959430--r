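#' Feature-class and feature-feature correlations for CFS
#'
#' Computes the correlation structure that the subset merit consumes. With
#' `measure = "symmetric_uncertainty"` (default), continuous features are
#' discretized by equal-frequency binning (10 bins) and the symmetric
#' uncertainty `SU(X, Y) = 2 I(X; Y) / (H(X) + H(Y))` is used, which lies in
#' `[0, 1]`. With `measure = "pearson_abs"`, absolute Pearson correlations
#' are used; the feature-class correlation is the mean of `|cor|` with the
#' one-vs-rest indicator of each class.
#'
#' @param table Feature tibble as produced by [extract_feature_table()]: a
#'   `label` column plus feature columns (non-feature bookkeeping columns
#'   `subject`, `repetition`, `window_id` are ignored).
#' @param measure `"symmetric_uncertainty"` or `"pearson_abs"`.
#' @param bins Number of equal-frequency bins for discretization.
#' @return A `kdemg_correlations` object: list with `feature_class` (named
#'   vector), `feature_feature` (named symmetric matrix, unit diagonal), and
#'   `measure`.
#' @export
compute_correlations <- function(table,
                                 measure = c("symmetric_uncertainty",
                                             "pearson_abs"),
                                 bins = 10L) {
  measure <- match.arg(measure)
  feat_cols <- setdiff(names(table), c("subject", "label", "repetition",
                                       "window_id"))
  if (length(feat_cols) < 2) {
    abort("Need at least two features.", class = "kdemg_error_bad_input")
  }
  y <- table$label
  if (length(unique(y)) < 2) {
    abort("Need at least two classes.", class = "kdemg_error_bad_input")
  }
  X <- as.matrix(table[feat_cols])
  p <- ncol(X)
  const <- apply(X, 2L, function(x) length(unique(x)) == 1L)
  if (any(const)) {
    warn(sprintf("Constant feature(s): %s; correlations set to 0.",
                 paste(feat_cols[const], collapse = ", ")),
         class = "kdemg_warning_constant_feature")
  }
  if (measure == "symmetric_uncertainty") {
    D <- lapply(seq_len(p), function(j) discretize_ef(X[, j], bins))
    rcf <- vapply(seq_len(p), function(j) {
      if (const[j]) 0 else symmetric_uncertainty(D[[j]], y)
    }, numeric(1))
    rff <- diag(1, p)
    for (j in seq_len(p - 1)) {
      for (k in (j + 1):p) {
        v <- if (const[j] || const[k]) 0 else
          symmetric_uncertainty(D[[j]], D[[k]])
        rff[j, k] <- rff[k, j] <- v
      }
    }
  } else {
    classes <- sort(unique(y))
    rcf <- vapply(seq_len(p), function(j) {
      if (const[j]) return(0)
      mean(vapply(classes, function(cl) {
        abs(cor(X[, j], as.numeric(y == cl)))
      }, numeric(1)))
    }, numeric(1))
    rff <- diag(1, p)
    if (sum(!const) > 1) {
      rff[!const, !const] <- abs(stats::cor(X[, !const, drop = FALSE]))
    }
    diag(rff) <- 1
  }
  names(rcf) <- feat_cols
  dimnames(rff) <- list(feat_cols, feat_cols)
  structure(list(feature_class = rcf, feature_feature = rff,
                 measure = measure),
            class = "kdemg_correlations")
}

# Equal-frequency discretization; identical values always share a bin, so a
# feature that is a relabelling of the class reaches SU = 1.
discretize_ef <- function(x, bins) {
  ux <- unique(x)
  if (length(ux) <= bins) return(match(x, sort(ux)))
  br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1),
                        names = FALSE, type = 7))
  findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
}

shannon_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

symmetric_uncertainty <- function(x, y) {
  tab <- table(x, y)
  hx <- shannon_entropy(rowSums(tab))
  hy <- shannon_entropy(colSums(tab))
  if (hx + hy == 0) return(0)
  hxy <- shannon_entropy(as.vector(tab))
  mi <- hx + hy - hxy
  2 * mi / (hx + hy)
}

#' CFS subset merit
#'
#' `Merit(S) = k * mean(r_cf) / sqrt(k + k (k - 1) * mean(r_ff))` for a
#' subset of `k` features, where `mean(r_cf)` is the average feature-class
#' correlation over the subset and `mean(r_ff)` the average feature-feature
#' correlation over its distinct pairs. High merit rewards subsets that are
#' relevant to the class but mutually non-redundant; for `k = 1` the merit
#' is the feature's class correlation.
#'
#' @param subset Character vector of feature names (or integer indices).
#' @param corr A `kdemg_correlations` object.
#' @return Merit (scalar).
#' @export
cfs_merit <- function(subset, corr) {
  nm <- names(corr$feature_class)
  idx <- if (is.character(subset)) match(subset, nm) else as.integer(subset)
  if (length(idx) == 0 || anyNA(idx)) {
    abort("Subset must be non-empty and present in the correlation object.",
          class = "kdemg_error_bad_input")
  }
  k <- length(idx)
  rcf <- mean(corr$feature_class[idx])
  if (k == 1) return(rcf)
  ff <- corr$feature_feature[idx, idx]
  rff <- mean(ff[upper.tri(ff)])
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

#' Best-first search over feature subsets
#'
#' Starts from the empty set, generates all single-feature expansions, and
#' repeatedly expands the highest-merit unexpanded subset on the open list,
#' backtracking when an expansion yields no improvement. The search stops
#' after `max_stale` consecutive fully expanded subsets that fail to improve
#' on the best merit seen (default 5). Ties on the open list are broken
#' lexicographically by feature-name sequence, so the search is
#' deterministic.
#'
#' @param corr A `kdemg_correlations` object from [compute_correlations()].
#' @param max_stale Consecutive non-improving expansions tolerated.
#' @param max_expansions Safety cap on the number of expanded subsets.
#' @return A `kdemg_selection` object: `selected` (feature names), `merit`,
#'   `trace` (tibble of expansion events), `stop_reason`.
#' @export
best_first_search <- function(corr, max_stale = 5L, max_expansions = 5000L) {
  nm <- names(corr$feature_class)
  p <- length(nm)
  if (p < 1) abort("No features.", class = "kdemg_error_bad_input")

  key_of <- function(idx) paste(idx, collapse = ",")
  seen <- new.env(parent = emptyenv())
  # open list kept as parallel vectors: keys, merits; subsets in a list
  open_keys <- character()
  open_merit <- numeric()
  open_sets <- list()

  push <- function(idx, merit) {
    k <- key_of(idx)
    if (!is.null(seen[[k]])) return(invisible(NULL))
    assign(k, TRUE, envir = seen)
    open_keys[[length(open_keys) + 1L]] <<- k
    open_merit[[length(open_merit) + 1L]] <<- merit
    open_sets[[length(open_sets) + 1L]] <<- idx
  }

  pop_best <- function() {
    best_m <- max(open_merit)
    cand <- which(open_merit >= best_m - 1e-15)
    if (length(cand) > 1L) {
      ord <- order(vapply(open_sets[cand], function(s) {
        paste(sprintf("%04d", s), collapse = ",")
      }, character(1)))
      cand <- cand[ord]
    }
    i <- cand[1L]
    node <- list(idx = open_sets[[i]], merit = open_merit[[i]])
    open_keys <<- open_keys[-i]
    open_merit <<- open_merit[-i]
    open_sets <<- open_sets[-i]
    node
  }

  best_idx <- integer()
  best_merit <- -Inf
  stale <- 0L
  trace <- list()

  # expand the empty set: all singletons
  for (j in seq_len(p)) push(j, cfs_merit(j, corr))
  expansions <- 0L
  stop_reason <- "exhausted"

  while (length(open_merit) > 0L) {
    node <- pop_best()
    if (node$merit > best_merit + 1e-12) {
      best_merit <- node$merit
      best_idx <- node$idx
    }
    # fully expand the node
    improved <- FALSE
    for (j in setdiff(seq_len(p), node$idx)) {
      child <- sort(c(node$idx, j))
      k <- key_of(child)
      if (!is.null(seen[[k]])) next
      m <- cfs_merit(child, corr)
      push(child, m)
      if (m > best_merit + 1e-12) {
        best_merit <- m
        best_idx <- child
        improved <- TRUE
      }
    }
    expansions <- expansions + 1L
    trace[[expansions]] <- tibble(
      step = expansions, subset = paste(nm[node$idx], collapse = "+"),
      merit = node$merit, improved = improved)
    stale <- if (improved) 0L else stale + 1L
    if (stale >= max_stale) { stop_reason <- "stale"; break }
    if (expansions >= max_expansions) { stop_reason <- "cap"; break }
  }

  structure(
    list(selected = nm[best_idx], merit = best_merit,
         trace = dplyr::bind_rows(trace), stop_reason = stop_reason),
    class = "kdemg_selection"
  )
}

#' @export
print.kdemg_selection <- function(x, ...) {
  cat(sprintf("<kdemg_selection> %d feature(s), merit %.4f (stop: %s)\n",
              length(x$selected), x$merit, x$stop_reason))
  cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.kdemg_selection <- function(x, ...) x$trace

#' @export
glance.kdemg_selection <- function(x, ...) {
  tibble(n_selected = length(x$selected), merit = x$merit,
         stop_reason = x$stop_reason, n_expanded = nrow(x$trace))
}
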