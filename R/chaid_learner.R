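#' CHAID decision-tree learning of case definitions
#'
#' Chi-square Automatic Interaction Detection (CHAID) learns a decision
#' tree over categorical features (here, binary presence indicators for
#' code atoms) against a binary frail/not-frail label. At each node, each
#' feature's categories are merged stepwise — the pair of category groups
#' with the largest pairwise chi-square p-value is merged while that
#' p-value exceeds `alpha_merge` — and the feature with the smallest
#' Bonferroni-adjusted split p-value splits the node when it passes
#' `alpha_split`, children are large enough, and the depth budget allows.
#' The Bonferroni multiplier is the number of ways the original
#' categories can collapse into the merged group count (a Stirling number
#' of the second kind). Complexity parameters are selected by bootstrap
#' out-of-bag misclassification and validity is reported from stratified
#' k-fold cross-validation with exact (Clopper-Pearson) confidence
#' intervals.
#'
#' @name chaid_learner
NULL

#' CHAID complexity parameters
#'
#' @param alpha_merge Merge threshold (default 0.05).
#' @param alpha_split Split threshold on the adjusted p-value (default 0.05).
#' @param min_node_size Minimum rows in any child (default 25).
#' @param max_depth Maximum tree depth; 0 = root only (default 3).
#' @param bonferroni Apply the Bonferroni multiplier (default `TRUE`).
#' @return A `chaid_params` object.
#' @export
chaid_params <- function(alpha_merge = 0.05, alpha_split = 0.05,
                         min_node_size = 25, max_depth = 3,
                         bonferroni = TRUE) {
  stopifnot(alpha_merge > 0, alpha_merge < 1, alpha_split > 0, alpha_split < 1,
            min_node_size >= 1, max_depth >= 0)
  structure(list(alpha_merge = alpha_merge, alpha_split = alpha_split,
                 min_node_size = as.integer(min_node_size),
                 max_depth = as.integer(max_depth),
                 bonferroni = isTRUE(bonferroni)),
            class = "chaid_params")
}

# Stirling number of the second kind S(n, k).
stirling2 <- function(n, k) {
  if (k == 0) return(as.numeric(n == 0))
  if (k > n) return(0)
  s <- matrix(0, n + 1, k + 1)
  s[1, 1] <- 1
  for (i in seq_len(n)) {
    for (j in seq_len(min(i, k))) {
      s[i + 1, j + 1] <- j * s[i, j + 1] + s[i, j]
    }
  }
  s[n + 1, k + 1]
}

chisq_p_groups <- function(group_idx, y) {
  tab <- table(group_idx, y)
  cs <- chisq_nocorrect(tab)
  list(p = cs$p, statistic = cs$statistic)
}

# Stepwise category merging for one feature at one node.
merge_categories <- function(x, y, alpha_merge) {
  groups <- lapply(sort(unique(as.character(x))), identity)
  while (length(groups) > 2) {
    npair <- utils::combn(length(groups), 2)
    pvals <- apply(npair, 2, function(pr) {
      sel <- x %in% c(groups[[pr[1]]], groups[[pr[2]]])
      gi <- ifelse(x[sel] %in% groups[[pr[1]]], 1L, 2L)
      chisq_p_groups(gi, y[sel])$p
    })
    worst <- which.max(pvals)
    if (pvals[worst] <= alpha_merge) break
    a <- npair[1, worst]; b <- npair[2, worst]
    groups[[a]] <- c(groups[[a]], groups[[b]])
    groups[[b]] <- NULL
  }
  groups
}

node_candidate <- function(x, y, params) {
  n_orig <- length(unique(as.character(x)))
  if (n_orig < 2) return(NULL)
  groups <- merge_categories(x, y, params$alpha_merge)
  gi <- group_index(x, groups)
  cs <- chisq_p_groups(gi, y)
  mult <- if (params$bonferroni) stirling2(n_orig, length(groups)) else 1
  list(groups = groups, p_adj = min(1, cs$p * mult), statistic = cs$statistic,
       sizes = tabulate(gi, nbins = length(groups)))
}

group_index <- function(x, groups) {
  xi <- as.character(x)
  gi <- rep(NA_integer_, length(xi))
  for (g in seq_along(groups)) gi[xi %in% groups[[g]]] <- g
  gi
}

grow_node <- function(features, y, params, depth, node_id_env) {
  node_id_env$next_id <- node_id_env$next_id + 1L
  id <- node_id_env$next_id
  n <- length(y)
  n_frail <- sum(y)
  leaf <- function() {
    list(id = id, n = n, n_frail = n_frail, prob_frail = n_frail / n,
         is_leaf = TRUE)
  }
  if (depth >= params$max_depth || n_frail == 0 || n_frail == n) {
    return(leaf())
  }
  best <- NULL
  for (f in names(features)) {
    cand <- node_candidate(features[[f]], y, params)
    if (is.null(cand)) next
    if (cand$p_adj > params$alpha_split) next
    if (min(cand$sizes) < params$min_node_size) next
    if (is.null(best) || cand$p_adj < best$p_adj) {
      best <- c(cand, list(feature = f))
    }
  }
  if (is.null(best)) return(leaf())
  gi <- group_index(features[[best$feature]], best$groups)
  children <- lapply(seq_along(best$groups), function(g) {
    sel <- gi == g
    grow_node(features[sel, , drop = FALSE], y[sel], params, depth + 1,
              node_id_env)
  })
  list(id = id, n = n, n_frail = n_frail, prob_frail = n_frail / n,
       is_leaf = FALSE, feature = best$feature, groups = best$groups,
       statistic = best$statistic, p_adj = best$p_adj, children = children)
}

#' Fit a CHAID tree
#'
#' @param features Data frame of categorical features (factor, character
#'   or logical columns; logicals are treated as `"TRUE"`/`"FALSE"`).
#' @param labels Logical (or coercible 0/1) vector: `TRUE` = frail.
#' @param params A [chaid_params()].
#' @return An object of class `chaid_tree`.
#' @export
fit_chaid <- function(features, labels, params = chaid_params()) {
  stopifnot(inherits(params, "chaid_params"))
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (nrow(features) < 2 || ncol(features) < 1) {
    abort("need at least 2 rows and 1 feature")
  }
  for (f in names(features)) {
    v <- features[[f]]
    if (is.numeric(v) && !all(v %in% c(0, 1))) {
      abort(sprintf("feature '%s' is not categorical", f))
    }
    features[[f]] <- as.character(v)
  }
  y <- as.logical(labels)
  if (anyNA(y)) abort("labels must be binary with no missing values")
  env <- new.env()
  env$next_id <- 0L
  root <- grow_node(features, y, params, 0L, env)
  structure(list(root = root, params = params,
                 feature_names = names(features), n = length(y)),
            class = "chaid_tree")
}

route_rows <- function(node, features, idx, out) {
  if (node$is_leaf || length(idx) == 0) {
    out$prob[idx] <- node$prob_frail
    return(out)
  }
  gi <- group_index(features[[node$feature]][idx], node$groups)
  unseen <- is.na(gi)
  out$prob[idx[unseen]] <- node$prob_frail
  for (g in seq_along(node$children)) {
    out <- route_rows(node$children[[g]], features, idx[which(gi == g)], out)
  }
  out
}

#' @param object A `chaid_tree`.
#' @param newdata Data frame of features.
#' @param type `"prob"` for P(frail) or `"class"` for a logical call at 0.5.
#' @param ... Unused.
#' @rdname fit_chaid
#' @export
predict.chaid_tree <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata, stringsAsFactors = FALSE)
  for (f in object$feature_names) {
    if (!f %in% names(newdata)) abort(sprintf("missing feature '%s'", f))
    newdata[[f]] <- as.character(newdata[[f]])
  }
  out <- list(prob = rep(NA_real_, nrow(newdata)))
  out <- route_rows(object$root, newdata, seq_len(nrow(newdata)), out)
  if (type == "prob") out$prob else out$prob > 0.5
}

#' @export
print.chaid_tree <- function(x, ...) {
  rec <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$is_leaf) {
      cat(sprintf("%s* leaf n=%d P(frail)=%.3f\n", pad, node$n, node$prob_frail))
    } else {
      cat(sprintf("%s- split on %s (X2=%.2f, adj p=%.3g)\n", pad, node$feature,
                  node$statistic, node$p_adj))
      for (g in seq_along(node$children)) {
        cat(sprintf("%s  [%s]:\n", pad,
                    paste(node$groups[[g]], collapse = ",")))
        rec(node$children[[g]], indent + 2)
      }
    }
  }
  cat(sprintf("<chaid_tree> n=%d\n", x$n))
  rec(x$root, 0)
  invisible(x)
}

#' Select complexity parameters by bootstrap out-of-bag misclassification
#'
#' Each candidate is fitted on `n_boot` bootstrap resamples and scored on
#' the out-of-bag rows; the candidate with the smallest average
#' misclassification rate wins. Ties break toward simpler trees: smaller
#' `max_depth`, then larger `min_node_size`.
#'
#' @param features,labels As in [fit_chaid()].
#' @param grid List of [chaid_params()] candidates.
#' @param n_boot Number of bootstrap resamples (default 25).
#' @param seed Integer seed for resampling.
#' @return The winning `chaid_params`, with attributes `oob` (per-candidate
#'   average misclassification) and `selected` (index).
#' @export
bootstrap_select <- function(features, labels, grid, n_boot = 25, seed = 1) {
  stopifnot(length(grid) >= 1, n_boot >= 1)
  y <- as.logical(labels)
  n <- length(y)
  set.seed(seed)
  resamples <- lapply(seq_len(n_boot), function(b) sample.int(n, replace = TRUE))
  oob_rate <- vapply(grid, function(params) {
    rates <- vapply(resamples, function(idx) {
      oob <- setdiff(seq_len(n), unique(idx))
      if (length(oob) == 0) return(NA_real_)
      fit <- fit_chaid(features[idx, , drop = FALSE], y[idx], params)
      mean(predict(fit, features[oob, , drop = FALSE]) != y[oob])
    }, numeric(1))
    mean(rates, na.rm = TRUE)
  }, numeric(1))
  depth <- vapply(grid, `[[`, numeric(1), "max_depth")
  minsz <- vapply(grid, `[[`, numeric(1), "min_node_size")
  ord <- order(oob_rate, depth, -minsz)
  winner <- grid[[ord[1]]]
  attr(winner, "oob") <- oob_rate
  attr(winner, "selected") <- ord[1]
  winner
}

#' Cross-validated validity of a CHAID case definition
#'
#' Stratified k-fold cross-validation; out-of-fold predictions are pooled
#' into a single confusion matrix from which sensitivity, specificity,
#' PPV and NPV with exact confidence intervals are computed.
#'
#' @param features,labels As in [fit_chaid()].
#' @param params A [chaid_params()].
#' @param k Number of folds (default 10; `k = n` gives leave-one-out).
#' @param seed Integer seed for fold assignment.
#' @return A [validity_metrics()] report with the pooled confusion matrix
#'   in its `confusion` element.
#' @export
cross_validate <- function(features, labels, params = chaid_params(), k = 10,
                           seed = 1) {
  y <- as.logical(labels)
  n <- length(y)
  stopifnot(k >= 2, k <= n)
  set.seed(seed)
  fold <- integer(n)
  for (cls in c(TRUE, FALSE)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  pred <- logical(n)
  for (f in seq_len(k)) {
    test <- which(fold == f)
    train <- which(fold != f)
    if (length(unique(y[train])) < 2) {
      warn(sprintf("fold %d: training labels constant; predicting majority", f))
      pred[test] <- mean(y[train]) > 0.5
      next
    }
    fit <- fit_chaid(features[train, , drop = FALSE], y[train], params)
    pred[test] <- predict(fit, features[test, , drop = FALSE])
  }
  report <- validity_metrics(tp = sum(pred & y), fp = sum(pred & !y),
                             tn = sum(!pred & !y), fn = sum(!pred & y))
  report$confusion <- c(tp = sum(pred & y), fp = sum(pred & !y),
                        tn = sum(!pred & !y), fn = sum(!pred & y))
  report
}

clopper_pearson <- function(x, n, conf_level = 0.95) {
  alpha <- 1 - conf_level
  lower <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Validity metrics from a confusion matrix
#'
#' Sensitivity, specificity, positive and negative predictive values with
#' exact (Clopper-Pearson) 95% confidence intervals.
#'
#' @param tp,fp,tn,fn Nonnegative integer cell counts; `tp + fn >= 1` and
#'   `tn + fp >= 1`.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `validity_report`: for each metric a list
#'   `est`, `lower`, `upper` (`NA` with a warning when a predictive
#'   value's denominator is zero).
#' @export
validity_metrics <- function(tp, fp, tn, fn, conf_level = 0.95) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fn >= 1, tn + fp >= 1)
  metric <- function(x, n, name) {
    if (n == 0) {
      warn(sprintf("%s undefined: empty denominator", name))
      return(list(est = NA_real_, lower = NA_real_, upper = NA_real_))
    }
    ci <- clopper_pearson(x, n, conf_level)
    list(est = x / n, lower = unname(ci["lower"]), upper = unname(ci["upper"]))
  }
  structure(list(
    sensitivity = metric(tp, tp + fn, "sensitivity"),
    specificity = metric(tn, tn + fp, "specificity"),
    ppv = metric(tp, tp + fp, "ppv"),
    npv = metric(tn, tn + fn, "npv"),
    conf_level = conf_level
  ), class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  cat(sprintf("<validity_report> (%.0f%% exact CIs)\n", 100 * x$conf_level))
  for (m in c("sensitivity", "specificity", "ppv", "npv")) {
    v <- x[[m]]
    cat(sprintf("  %-12s %.3f (%.3f-%.3f)\n", m, v$est, v$lower, v$upper))
  }
  invisible(x)
}

#' Standard learner feature atoms
#'
#' The EMR-definition ingredients plus the eight condition code families,
#' all as binary presence indicators.
#'
#' @return Named list of atom specifications.
#' @export
reference_atoms <- function() {
  a <- list(
    dementia_dx = list(kind = "icd9_prefix", values = "290"),
    furosemide_rx = list(kind = "atc_prefix", values = "C03CA01"),
    vitamins_rx = list(kind = "atc_prefix", values = "A11"),
    obstruction_text = list(kind = "text_keyword", values = "obstruction")
  )
  for (cn in COND_NAMES) {
    a[[paste0("cond_", cn)]] <- list(kind = "icd9_prefix",
                                     values = COND_ICD9_EMIT[[cn]])
  }
  a
}

#' Build a labeled reference set from an EMR bundle and ground truth
#'
#' Features are binary presence indicators ("code atom observed in the
#' lookback window") for the EMR-definition ingredients and the eight
#' condition code families; the label is the generator's true frailty.
#'
#' @param emr_bundle An EMR `frail_bundle`.
#' @param truth Truth table from [generate_cohort()].
#' @param index_year Index calendar year.
#' @param lookback_years Window length (default 6).
#' @param atoms Named atom list (default: standard feature atoms).
#' @return List with `features` (data frame of `"0"`/`"1"` factors),
#'   `labels` (logical), `person_id`.
#' @export
build_reference_set <- function(emr_bundle, truth, index_year,
                                lookback_years = 6, atoms = reference_atoms()) {
  window <- c(year_start(index_year - lookback_years + 1),
              year_end(index_year))
  ids <- emr_bundle$persons$person_id
  features <- lapply(atoms, function(a) {
    hits <- atom_event_hits(a, emr_bundle$claims, emr_bundle$prescriptions,
                            window)
    factor(ifelse(ids %in% hits$person_id, "1", "0"), levels = c("0", "1"))
  })
  labels <- truth$truly_frail[match(ids, truth$person_id)]
  list(features = as.data.frame(features, stringsAsFactors = FALSE),
       labels = labels, person_id = ids)
}

#' Convert a CHAID tree into a case definition
#'
#' Leaves with majority frail class become OR-ed conjunctions of their
#' path conditions (`feature present` / `not present`), yielding a rule
#' usable by [apply_emr_definition()].
#'
#' @param tree A `chaid_tree` fitted on binary presence features.
#' @param atoms Named atom list defining each feature (default: the
#'   standard reference atoms).
#' @param lookback_years Lookback for the resulting definition.
#' @return A [case_definition()], or `NULL` if no leaf is majority-frail.
#' @export
as_case_definition <- function(tree, atoms = reference_atoms(),
                               lookback_years = 6) {
  paths <- list()
  walk <- function(node, conds) {
    if (node$is_leaf) {
      if (node$prob_frail > 0.5) paths[[length(paths) + 1]] <<- conds
      return(invisible(NULL))
    }
    for (g in seq_along(node$children)) {
      grp <- node$groups[[g]]
      cond <- if (identical(grp, "1")) node$feature
        else if (identical(grp, "0")) list("not", node$feature)
        else NULL  # merged both levels: no constraint
      walk(node$children[[g]], c(conds, if (!is.null(cond)) list(cond)))
    }
  }
  walk(tree$root, list())
  if (length(paths) == 0) return(NULL)
  to_expr <- function(conds) {
    if (length(conds) == 0) abort("majority-frail root leaf has no conditions")
    if (length(conds) == 1) conds[[1]] else c(list("and"), conds)
  }
  expr <- if (length(paths) == 1) to_expr(paths[[1]]) else
    c(list("or"), lapply(paths, to_expr))
  used <- collect_atom_refs(expr)
  case_definition(atoms[used], expr, lookback_years)
}
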