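#' Within-group coefficient of variation, small-sample corrected
#'
#' `CVw = 100 * (sd / mean) * (1 + 1/(4n))`, with the standard deviation on
#' the `n - 1` denominator. The correction factor compensates the downward
#' bias of the CV in small groups.
#'
#' @param values Numeric vector of one group's values (length >= 2).
#' @return CV in percent.
#' @export
cv_within <- function(values) {
  n <- length(values)
  if (n < 2) stop_invalid("cv_within needs at least 2 values")
  m <- mean(values)
  if (!is.finite(m) || m <= 0)
    stop(structure(class = c("callcontext_undefined_cv", "error", "condition"),
                   list(message = "CV undefined: group mean <= 0", call = sys.call())))
  100 * (sd(values) / m) * (1 + 1 / (4 * n))
}

#' Between-group coefficient of variation
#'
#' `CVb = 100 * sd / mean` over the pooled sample (no small-sample
#' correction).
#'
#' @param values Numeric vector of all values pooled across groups.
#' @return CV in percent.
#' @export
cv_between <- function(values) {
  m <- mean(values)
  if (!is.finite(m) || m <= 0)
    stop(structure(class = c("callcontext_undefined_cv", "error", "condition"),
                   list(message = "CV undefined: pooled mean <= 0", call = sys.call())))
  100 * sd(values) / m
}

#' Potential of Contextual Coding for one feature
#'
#' `PCC = CVb / mean(CVw)`, where `mean(CVw)` is the unweighted arithmetic
#' mean of the per-context corrected within-group CVs. A PCC at or above 1
#' flags a feature whose between-context variation exceeds its typical
#' within-context variation, i.e. a candidate carrier of context
#' information.
#'
#' @param values Numeric vector of the feature's values.
#' @param groups Context label per value (>= 2 contexts, each with >= 2
#'   observations).
#' @return One-row data frame: `cvb`, `mean_cvw`, `pcc`, `n_total`,
#'   `defined`, plus per-context `cvw_<ctx>` and `n_<ctx>` columns.
#' @export
pcc_index <- function(values, groups) {
  groups <- as.character(groups)
  ok <- is.finite(values)
  values <- values[ok]; groups <- groups[ok]
  split_vals <- split(values, groups)
  if (length(split_vals) < 2)
    stop_invalid("pcc_index needs at least 2 contexts")
  if (any(vapply(split_vals, length, 0L) < 2))
    stop_invalid("every context needs at least 2 observations")
  res <- tryCatch({
    cvws <- vapply(split_vals, cv_within, numeric(1))
    cvb <- cv_between(values)
    mean_cvw <- mean(cvws)
    pcc <- if (mean_cvw > 0) cvb / mean_cvw else NA_real_
    list(cvb = cvb, mean_cvw = mean_cvw, pcc = pcc, cvws = cvws,
         defined = is.finite(pcc))
  }, callcontext_undefined_cv = function(e) {
    list(cvb = NA_real_, mean_cvw = NA_real_, pcc = NA_real_,
         cvws = setNames(rep(NA_real_, length(split_vals)), names(split_vals)),
         defined = FALSE)
  })
  out <- data.frame(cvb = res$cvb, mean_cvw = res$mean_cvw, pcc = res$pcc,
                    n_total = length(values), defined = res$defined)
  for (ctx in names(split_vals)) {
    out[[paste0("cvw_", ctx)]] <- unname(res$cvws[ctx])
    out[[paste0("n_", ctx)]] <- length(split_vals[[ctx]])
  }
  out
}

#' PCC table over all features of a feature table
#'
#' @param table A `feature_table` (or data frame with a `context` column).
#' @param features Feature columns to index (default [feature_names]).
#' @return Data frame, one row per feature, as returned by [pcc_index] plus
#'   a leading `feature` column.
#' @export
pcc_table <- function(table, features = feature_names(table)) {
  rows <- lapply(features, function(f) {
    cbind(data.frame(feature = f, stringsAsFactors = FALSE),
          pcc_index(table[[f]], table$context))
  })
  do.call(rbind, rows)
}

#' Balance a feature table by caller and context
#'
#' Caps every (caller, context) cell at `max_per` rows, sampling without
#' replacement, to prevent any individual dominating a context and biasing
#' the coding indices (pseudo-replication control).
#'
#' @param table A `feature_table` with `caller_id` and `context` columns.
#' @param max_per Maximum rows retained per (caller, context) cell.
#' @param seed Integer seed for the subsampling.
#' @return The balanced table; removed rows are reported in the
#'   `removed` attribute (a data frame of call ids with their cell).
#' @export
balance_by_caller <- function(table, max_per, seed = 1L) {
  stopifnot(all(c("caller_id", "context") %in% names(table)))
  cell <- interaction(table$caller_id, table$context, drop = TRUE)
  keep <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(table)), cell), function(idx) {
      if (length(idx) <= max_per) idx else sort(sample(idx, max_per))
    }), use.names = FALSE)
  })
  keep <- sort(keep)
  removed <- setdiff(seq_len(nrow(table)), keep)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- data.frame(
    call_id = table$call_id[removed],
    caller_id = table$caller_id[removed],
    context = table$context[removed], stringsAsFactors = FALSE)
  attr(out, "settings") <- attr(table, "settings")
  class(out) <- class(table)
  out
}

#' Three-step feature selection
#'
#' Reproduces the selection cascade applied before discriminant analysis:
#' (i) keep features with `PCC >= pcc_threshold`; (ii) drop features whose
#' pooled values fail a Shapiro-Wilk normality test at `alpha_normality`
#' (or whose every context fails, with `normality = "per_context"`);
#' (iii) cluster the survivors by absolute Pearson correlation
#' (single linkage, cut at `|r| >= redundancy_r`) and keep one
#' representative per cluster — the median-type variant of a
#' mean/median/sd family when one is present, otherwise the member with the
#' highest PCC. Every input feature is accounted for exactly once in the
#' audit trail.
#'
#' @param table A `feature_table`.
#' @param features Candidate feature columns (default [feature_names]).
#' @param pcc_threshold Minimum PCC retained at step (i).
#' @param alpha_normality Shapiro-Wilk significance level at step (ii).
#' @param redundancy_r Absolute-correlation threshold at step (iii).
#' @param normality `"pooled"` (default) tests pooled values; `"per_context"`
#'   requires every context to pass.
#' @return Data frame of class `selection_report`: feature, pcc, passed_pcc,
#'   shapiro_p, passed_normality, cluster, is_representative, retained,
#'   rationale. Attribute `retained` holds the retained feature names.
#' @export
select_features <- function(table, features = feature_names(table),
                            pcc_threshold = 1.0, alpha_normality = 0.05,
                            redundancy_r = 0.9,
                            normality = c("pooled", "per_context")) {
  normality <- match.arg(normality)
  if (length(features) < 3) stop_invalid("select_features needs >= 3 features")
  pt <- pcc_table(table, features)
  complete <- vapply(features, function(f) all(is.finite(table[[f]])),
                     logical(1))
  rep_df <- data.frame(
    feature = pt$feature, pcc = pt$pcc,
    passed_pcc = complete & pt$defined & !is.na(pt$pcc) &
      pt$pcc >= pcc_threshold,
    shapiro_p = NA_real_, passed_normality = NA,
    cluster = NA_integer_, is_representative = NA, retained = FALSE,
    rationale = "", stringsAsFactors = FALSE
  )
  rep_df$rationale[!rep_df$passed_pcc] <-
    sprintf("dropped at step i: PCC %.3f < %.3f (or undefined)",
            rep_df$pcc[!rep_df$passed_pcc], pcc_threshold)
  rep_df$rationale[!complete] <-
    "dropped at step i: feature has missing values"
  rep_df$passed_pcc[!complete] <- FALSE

  shapiro_p_of <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 3 || sd(x) == 0) return(0)  # degenerate: not normal
    stats::shapiro.test(x)$p.value
  }
  for (i in which(rep_df$passed_pcc)) {
    f <- rep_df$feature[i]
    p <- if (normality == "pooled") {
      shapiro_p_of(table[[f]])
    } else {
      min(vapply(split(table[[f]], table$context), shapiro_p_of, numeric(1)))
    }
    rep_df$shapiro_p[i] <- p
    rep_df$passed_normality[i] <- p >= alpha_normality
    if (!rep_df$passed_normality[i])
      rep_df$rationale[i] <- sprintf(
        "dropped at step ii: Shapiro-Wilk p = %.4f < %.2f", p, alpha_normality)
  }

  surv <- which(rep_df$passed_pcc & rep_df$passed_normality %in% TRUE)
  if (length(surv) == 0) {
    attr(rep_df, "retained") <- character(0)
    class(rep_df) <- c("selection_report", "data.frame")
    return(rep_df)
  }
  feats <- rep_df$feature[surv]
  if (length(feats) == 1) {
    cl <- setNames(1L, feats)
  } else {
    cm <- suppressWarnings(stats::cor(as.matrix(table[feats])))
    cm[!is.finite(cm)] <- 0; diag(cm) <- 1
    hc <- stats::hclust(stats::as.dist(1 - abs(cm)), method = "single")
    cl <- stats::cutree(hc, h = 1 - redundancy_r)
  }
  rep_df$cluster[surv] <- cl[feats]
  for (g in unique(cl)) {
    members <- feats[cl == g]
    med <- grep("median", members, value = TRUE)
    cand <- if (length(med) > 0) med else members
    pccs <- rep_df$pcc[match(cand, rep_df$feature)]
    repr <- cand[which.max(pccs)]
    for (m in members) {
      i <- which(rep_df$feature == m)
      rep_df$is_representative[i] <- m == repr
      if (m == repr) {
        rep_df$retained[i] <- TRUE
        rep_df$rationale[i] <- sprintf(
          "retained: representative of redundancy cluster %d (%d member(s))",
          g, length(members))
      } else {
        rep_df$rationale[i] <- sprintf(
          "dropped at step iii: redundant with %s (cluster %d)", repr, g)
      }
    }
  }
  attr(rep_df, "retained") <- rep_df$feature[rep_df$retained]
  class(rep_df) <- c("selection_report", "data.frame")
  rep_df
}
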