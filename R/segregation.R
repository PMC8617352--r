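# Model-guided bean segregation: rank beans by a predicted attribute,
# pull out the extreme fractions, and compare the resulting batches on
# their true (reference) composition by one-way ANOVA with Tukey's HSD.

#' Select the extreme fractions of ranked predictions
#'
#' Deterministically picks the `ceiling(fraction * n)` beans with the
#' highest and lowest predicted values; ties are broken by bean id
#' order. An all-equal prediction vector is flagged as degenerate.
#'
#' @param predictions Named numeric vector (names = bean ids).
#' @param fraction Selection fraction per tail (default 0.10).
#' @return List with `high_ids`, `low_ids`, `k` and `degenerate`.
#' @export
rank_and_select <- function(predictions, fraction = 0.10) {
  n <- length(predictions)
  if (is.null(names(predictions)) || anyDuplicated(names(predictions)))
    stop("predictions must be uniquely named by bean id")
  k <- ceiling(fraction * n)
  if (k < 1 || 2 * k > n)
    stop("selection error: fraction ", fraction,
         " makes the high and low groups overlap (n = ", n, ")")
  ids <- names(predictions)
  high <- ids[order(-predictions, ids)][seq_len(k)]
  low <- ids[order(predictions, ids)][seq_len(k)]
  list(high_ids = high, low_ids = low, k = k,
       degenerate = length(unique(predictions)) == 1)
}

# Greedy insert-and-absorb compact letter display.
# groups_desc: group names ordered by descending mean;
# sig: symmetric logical matrix (TRUE = significantly different).
compact_letters <- function(groups_desc, sig) {
  cols <- list(groups_desc)  # start: one column holding all groups
  g <- length(groups_desc)
  for (i in seq_len(g - 1)) for (j in seq(i + 1, g)) {
    gi <- groups_desc[i]; gj <- groups_desc[j]
    if (!sig[gi, gj]) next
    for (ci in seq_along(cols)) {
      if (gi %in% cols[[ci]] && gj %in% cols[[ci]]) {
        a <- setdiff(cols[[ci]], gj)
        b <- setdiff(cols[[ci]], gi)
        cols[[ci]] <- a
        cols[[length(cols) + 1]] <- b
      }
    }
    # absorb columns that are subsets of another
    keep <- rep(TRUE, length(cols))
    for (ci in seq_along(cols)) for (cj in seq_along(cols)) {
      if (ci != cj && keep[ci] && keep[cj] &&
          all(cols[[ci]] %in% cols[[cj]]) &&
          !(all(cols[[cj]] %in% cols[[ci]]) && ci < cj))
        keep[ci] <- FALSE
    }
    cols <- cols[keep]
  }
  # letter columns ordered by the best-ranked group they contain
  first_rank <- vapply(cols, function(cc)
    min(match(cc, groups_desc)), numeric(1))
  cols <- cols[order(first_rank)]
  letters_out <- stats::setNames(rep("", g), groups_desc)
  for (ci in seq_along(cols))
    for (gg in cols[[ci]])
      letters_out[gg] <- paste0(letters_out[gg], letters[ci])
  letters_out
}

#' Compare groups by one-way ANOVA and Tukey's HSD
#'
#' Runs a one-way ANOVA over the groups and, pairwise, Tukey's honestly
#' significant difference test at `alpha`; groups are summarised by a
#' compact letter display (greedy insert-and-absorb, letters assigned
#' in descending group-mean order, shared letter = not significantly
#' different).
#'
#' If every group has zero internal variance the comparison is flagged
#' as exact separation and letters follow the mean ordering directly.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each >= 2
#'   observations).
#' @param alpha Significance level (default 0.05).
#' @return List with `anova_p`, `tukey_p` (pairwise matrix), `letters`,
#'   `means`, `sds` and `exact_separation`.
#' @export
compare_groups <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 2)) stop("each group needs >= 2 observations")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be named")
  gnames <- names(groups)
  means <- vapply(groups, mean, numeric(1))
  sds <- vapply(groups, stats::sd, numeric(1))
  ord <- gnames[order(-means)]
  if (all(sds == 0)) {
    sig <- outer(means[ord], means[ord], function(a, b) a != b)
    dimnames(sig) <- list(ord, ord)
    return(list(anova_p = NA_real_, tukey_p = NULL,
                letters = compact_letters(ord, sig)[gnames],
                means = means, sds = sds, exact_separation = TRUE))
  }
  df <- data.frame(y = unlist(groups, use.names = FALSE),
                   g = factor(rep(gnames, lengths(groups)), levels = gnames))
  fit <- stats::aov(y ~ g, data = df)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$g
  tukey_p <- matrix(1, length(gnames), length(gnames),
                    dimnames = list(gnames, gnames))
  for (rn in rownames(tk)) {
    pair <- strsplit(rn, "-", fixed = TRUE)[[1]]
    tukey_p[pair[1], pair[2]] <- tukey_p[pair[2], pair[1]] <- tk[rn, "p adj"]
  }
  sig <- tukey_p < alpha
  list(anova_p = anova_p, tukey_p = tukey_p,
       letters = compact_letters(ord, sig)[gnames],
       means = means, sds = sds, exact_separation = FALSE)
}

#' Run a model-guided segregation trial
#'
#' Predicts the target attribute for every bean from its (pre-treated)
#' spectrum, selects the highest and lowest `fraction` of beans, and
#' compares High / Low / Remainder batches on their true chemical-class
#' and odorant-series sums computed from the reference profiles.
#'
#' @param X beans x bands pre-treated spectra, rownames = bean ids.
#' @param model A `pls_model` whose responses include `target`, or a
#'   named per-bean prediction vector (e.g. an oracle ranking) used
#'   as-is.
#' @param target Response name to sort on.
#' @param true_profiles beans x compounds matrix of reference relative
#'   peak areas (%), rownames matching `X`.
#' @param roster Compound roster.
#' @param fraction Selection fraction per tail.
#' @param alpha Significance level for the group comparisons.
#' @return A `segregation_result`: target, fraction, id sets, per-
#'   attribute group means/sds, `anova_p` and Tukey `letters`.
#' @export
run_segregation_trial <- function(X, model, target, true_profiles,
                                  roster = load_roster(), fraction = 0.10,
                                  alpha = 0.05) {
  if (is.null(rownames(X))) stop("X needs bean ids as rownames")
  if (!all(rownames(X) %in% rownames(true_profiles)))
    stop("true_profiles is missing beans present in X")
  if (inherits(model, "pls_model")) {
    pred <- predict(model, X)
    colnames(pred) <- model$response_names
    if (!(target %in% colnames(pred)))
      stop("lookup error: model has no response '", target, "'")
    scores <- stats::setNames(pred[, target], rownames(X))
  } else {
    if (is.null(names(model)) || !all(rownames(X) %in% names(model)))
      stop("prediction vector must be named by bean id")
    pred <- matrix(model[rownames(X)], dimnames = list(rownames(X), target))
    scores <- model[rownames(X)]
  }
  sel <- rank_and_select(scores, fraction)
  grp <- rep("Remainder", nrow(X))
  names(grp) <- rownames(X)
  grp[sel$high_ids] <- "High"
  grp[sel$low_ids] <- "Low"

  prof <- true_profiles[rownames(X), , drop = FALSE]
  class_sums <- t(apply(prof, 1, group_by_class, roster = roster))
  desc_sums <- t(apply(prof, 1, group_by_descriptor, roster = roster))
  attrs <- cbind(class_sums, desc_sums)
  attrs <- attrs[, apply(attrs, 2, stats::sd) > 0 |
                   colSums(attrs) > 0, drop = FALSE]

  comparisons <- lapply(colnames(attrs), function(a) {
    compare_groups(split(attrs[, a], grp), alpha = alpha)
  })
  names(comparisons) <- colnames(attrs)
  summary_tab <- do.call(rbind, lapply(colnames(attrs), function(a) {
    cmp <- comparisons[[a]]
    data.frame(attribute = a,
               group = names(cmp$means),
               mean = as.numeric(cmp$means),
               sd = as.numeric(cmp$sds),
               letters = as.character(cmp$letters),
               anova_p = cmp$anova_p,
               row.names = NULL)
  }))
  structure(list(target = target, fraction = fraction,
                 high_ids = sel$high_ids, low_ids = sel$low_ids,
                 degenerate = sel$degenerate,
                 predictions = pred[, target],
                 groups = grp, attributes = attrs,
                 comparisons = comparisons, summary = summary_tab),
            class = "segregation_result")
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(sprintf("<segregation_result> target=%s fraction=%.2f (%d high, %d low)\n",
              x$target, x$fraction, length(x$high_ids), length(x$low_ids)))
  tgt <- x$summary[x$summary$attribute == x$target, ]
  if (nrow(tgt)) print(tgt, row.names = FALSE)
  invisible(x)
}
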