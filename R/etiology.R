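#' The published etiology decision tree
#'
#' The fixed classification tree relating cementum apposition patterns to
#' the five etiological groups (hyperfunctional HYPER, hypofunctional
#' HYPO, impacted IMP, infected INF, mixed MIX). Routing:
#' \itemize{
#'  \item preferential apposition (`pref`): yes vs no at the root;
#'  \item preferential side — antagonist present (`ant == 1`) gives a pure
#'    HYPER leaf; otherwise maximum cementum thickness at the 1295 um
#'    threshold isolates a pure MIX leaf (\eqn{\ge} 1295), then wear
#'    degree 0–2 isolates the pure IMP leaf and degrees 3+ a
#'    HYPER-majority leaf;
#'  \item non-preferential side — wear degree 0–1 (unscorable or unworn
#'    crown) gives the pure INF leaf; otherwise maximum vertical
#'    elevation below 190 um separates HYPO from MIX.
#' }
#'
#' @return A `decision_tree` whose splits are fixed; leaf counts are
#'   filled when routed over data (see [leaf_purity()]).
#' @export
published_tree <- function() {
  leaf <- function(id, label) list(type = "leaf", id = id, label = label)
  node <- function(var, kind, split, left, right, describe)
    list(type = "split", var = var, kind = kind, split = split,
         left = left, right = right, describe = describe)
  root <- node("pref", "categorical", list(levels_left = "1"),
    # preferential apposition
    node("ant", "categorical", list(levels_left = "1"),
         leaf("hyper_pure", "HYPER"),
         node("max_thi_um", "numeric", list(threshold = 1295, ge_right = TRUE),
              node("wear_deg", "numeric", list(threshold = 3, ge_right = TRUE),
                   leaf("imp_pure", "IMP"),
                   leaf("hyper_mix", "HYPER"),
                   "wear degree 0-2 vs 3+"),
              leaf("mix_thick", "MIX"),
              "MAX THI < 1295 um vs >= 1295 um"),
         "antagonist present vs lost/not scorable"),
    # non-preferential apposition
    node("wear_deg", "numeric", list(threshold = 2, ge_right = TRUE),
         leaf("inf_pure", "INF"),
         node("max_ve_um", "numeric", list(threshold = 190, ge_right = TRUE),
              leaf("hypo_pure", "HYPO"),
              leaf("mix_nonpref", "MIX"),
              "MAX VE < 190 um vs >= 190 um"),
         "wear degree 0-1 vs 2+"),
    "preferential vs non-preferential apposition")
  structure(list(root = root,
                 classes = c("HYPER", "HYPO", "IMP", "INF", "MIX"),
                 fitted = FALSE),
            class = "decision_tree")
}

route_one <- function(node, v, trace = character()) {
  while (node$type == "split") {
    val <- v[[node$var]]
    if (is.null(val) || (length(val) != 1) || is.na(val))
      return(list(leaf = NA_character_, label = "unroutable",
                  trace = c(trace, paste0(node$var, ": missing"))))
    if (node$kind == "numeric") {
      go_left <- val < node$split$threshold
      trace <- c(trace, sprintf("%s = %s %s %s", node$var, format(val),
                                if (go_left) "<" else ">=",
                                format(node$split$threshold)))
    } else {
      go_left <- as.character(val) %in% node$split$levels_left
      trace <- c(trace, sprintf("%s = %s %s {%s}", node$var,
                                as.character(val),
                                if (go_left) "in" else "not in",
                                paste(node$split$levels_left, collapse = ",")))
    }
    node <- if (go_left) node$left else node$right
  }
  list(leaf = node$id, label = node$label, trace = trace)
}

#' Apply the published decision tree to one tooth
#'
#' Routes a feature vector through the fixed published tree. Required
#' features depend on the path taken: `pref` always; `ant`,
#' `max_thi_um`, `wear_deg` on the preferential side; `wear_deg`,
#' `max_ve_um` on the non-preferential side. A missing value needed on
#' the traversed path yields an explicit `"unroutable"` result rather
#' than an imputation.
#'
#' @param v A list or one-row data frame with fields `pref` (logical or
#'   0/1), `ant` (factor/character 0–3), `max_thi_um`, `max_ve_um`,
#'   `wear_deg`.
#' @return A list with `leaf` (leaf id), `label` (majority etiology of
#'   that leaf) and `trace` (human-readable path).
#' @examples
#' apply_published_tree(list(pref = TRUE, ant = "1"))$label   # "HYPER"
#' @export
apply_published_tree <- function(v) {
  if (is.data.frame(v)) v <- as.list(v[1, ])
  if (is.logical(v$pref)) v$pref <- as.character(as.integer(v$pref))
  if (is.numeric(v$pref)) v$pref <- as.character(v$pref)
  if (!is.null(v$ant)) v$ant <- as.character(v$ant)
  route_one(published_tree()$root, v)
}

#' Route a feature table through a decision tree
#' @param tree A `decision_tree`.
#' @param data Data frame of feature vectors.
#' @return Data frame with `leaf`, `label` per row.
#' @export
route_tree <- function(tree, data) {
  stopifnot(inherits(tree, "decision_tree"))
  rows <- lapply(seq_len(nrow(data)), function(i) {
    v <- as.list(data[i, , drop = FALSE])
    if (is.logical(v$pref)) v$pref <- as.character(as.integer(v$pref))
    v <- lapply(v, function(x) if (is.factor(x)) as.character(x) else x)
    r <- route_one(tree$root, v)
    data.frame(leaf = r$leaf, label = r$label)
  })
  do.call(rbind, rows)
}

#' Leaf purity of a tree over labelled data
#'
#' Routes every record, tallies true labels per leaf, and reports the
#' number of pure leaves (all routed records share one label), the total
#' number of leaves reached, and the records whose label differs from
#' their leaf's majority label.
#'
#' @param tree A `decision_tree`.
#' @param data Feature data frame.
#' @param labels True class labels (defaults to `data$etiology`).
#' @param ids Record identifiers (defaults to `data$tooth_id`).
#' @return List with `n_pure`, `n_leaves`, `misclassified` (ids),
#'   `leaf_counts` (table leaf x label).
#' @export
leaf_purity <- function(tree, data, labels = data$etiology,
                        ids = data$tooth_id) {
  routed <- route_tree(tree, data)
  if (any(is.na(routed$leaf)))
    warning(sum(is.na(routed$leaf)), " unroutable records dropped")
  ok <- !is.na(routed$leaf)
  lab <- as.character(labels)[ok]
  leaf <- routed$leaf[ok]
  ids <- if (is.null(ids)) as.character(seq_along(labels))[ok] else
    as.character(ids)[ok]
  tab <- table(leaf = leaf, label = lab)
  n_pure <- sum(apply(tab, 1, function(r) sum(r > 0) == 1))
  maj <- colnames(tab)[apply(tab, 1, which.max)]
  names(maj) <- rownames(tab)
  mis <- ids[lab != maj[leaf]]
  list(n_pure = n_pure, n_leaves = nrow(tab), misclassified = mis,
       leaf_counts = tab)
}

#' Rule-based etiology classification (diagnostic criteria)
#'
#' Evaluates the published per-group diagnostic criteria against one
#' record and reports the fully matching group. The mixed-condition group
#' has no criteria of its own (it is defined by overlap), so it acts as
#' the fallback when two or more group profiles match fully; when none
#' does, the result is `"indeterminate"`. The trace reports, for each
#' group, how many of its criteria the record satisfies.
#'
#' Criteria: impacted — preferential apposition, no scorable antagonist,
#' unworn/uncarious/unexposed crown, stage-3 hypercementosis, maximum
#' thickness < 1295 um; infected — non-preferential apposition with pulp
#' exposure or caries; hypofunctional — non-preferential, wear degree 2–3,
#' stage-2 hypercementosis, maximum vertical elevation < 190 um;
#' hyperfunctional — preferential, stage-1 hypercementosis, wear degree
#' >= 6, no caries or pulp exposure, maximum thickness < 1295 um.
#'
#' @param record A one-row data frame in the `tooth_records` schema.
#' @return List with `etiology` (group code, `"MIX"` or
#'   `"indeterminate"`), `full_match` (character vector of fully matched
#'   groups) and `trace` (data frame group / matched / total).
#' @export
classify_table3 <- function(record) {
  if (is.data.frame(record)) record <- as.list(record[1, ])
  pref <- isTRUE(record$pref) || identical(record$pref, 1) ||
    identical(record$pref, "1")
  ant <- as.character(record$ant %||% NA)
  wear <- record$wear_deg
  caries <- !is.na(record$caries_si %||% NA)
  pulp <- !is.null(record$pulp_exp) && !is.na(record$pulp_exp) &&
    record$pulp_exp != "none"
  stage <- record$hc_stage
  thi <- record$max_thi_um
  ve <- record$max_ve_um

  crit <- list(
    IMP = c(pref = pref,
            no_antagonist = !is.na(ant) && ant == "0",
            no_lesion = !is.na(wear) && wear <= 1 && !caries && !pulp,
            stage3 = !is.na(stage) && stage == 3,
            thi_lt_1295 = !is.na(thi) && thi < 1295),
    INF = c(nonpref = !pref,
            pulp_or_caries = pulp || caries),
    HYPO = c(nonpref = !pref,
             wear_2_3 = !is.na(wear) && wear %in% 2:3,
             stage2 = !is.na(stage) && stage == 2,
             ve_lt_190 = !is.na(ve) && ve < 190),
    HYPER = c(pref = pref,
              stage1 = !is.na(stage) && stage == 1,
              wear_ge_6 = !is.na(wear) && wear >= 6,
              no_lesion = !caries && !pulp,
              thi_lt_1295 = !is.na(thi) && thi < 1295))
  matched <- vapply(crit, sum, 0L)
  total <- vapply(crit, length, 0L)
  full <- names(crit)[matched == total]
  etiology <- if (length(full) == 1) full
  else if (length(full) >= 2) "MIX"
  else "indeterminate"
  list(etiology = etiology, full_match = full,
       trace = data.frame(group = names(crit), matched = unname(matched),
                          total = unname(total)))
}

## ---- CART learner ----------------------------------------------------

gini_impurity <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts / n
  1 - sum(p^2)
}

# Best binary split of one predictor by Gini-impurity decrease.
# Numeric: thresholds at midpoints between sorted distinct values.
# Categorical: exhaustive proper subsets of observed levels (<= 8).
best_split_var <- function(x, y) {
  classes <- levels(y)
  n <- length(y)
  parent <- gini_impurity(table(y))
  best <- list(gain = -Inf)
  eval_split <- function(go_left, descr) {
    nl <- sum(go_left)
    if (nl == 0 || nl == n) return()
    gl <- gini_impurity(table(y[go_left]))
    gr <- gini_impurity(table(y[!go_left]))
    gain <- parent - (nl * gl + (n - nl) * gr) / n
    if (gain > best$gain + 1e-12)
      best <<- c(list(gain = gain), descr)
  }
  if (is.numeric(x)) {
    ux <- sort(unique(x))
    if (length(ux) >= 2) {
      thr <- (ux[-1] + ux[-length(ux)]) / 2
      for (t in thr) eval_split(x < t, list(kind = "numeric",
                                            split = list(threshold = t)))
    }
  } else {
    lev <- sort(unique(as.character(x)))
    k <- length(lev)
    if (k >= 2) {
      if (k > 8) stop("categorical predictors limited to 8 observed levels")
      # proper subsets containing the first level (avoids mirrored
      # duplicates): the other k-1 levels toggle freely, minus the case
      # where all of them join (the full set)
      for (mask in 0:(2^(k - 1) - 2)) {
        sel <- c(TRUE, bitwAnd(mask, 2^(seq_len(k - 1) - 1)) > 0)
        left_lev <- lev[sel]
        eval_split(as.character(x) %in% left_lev,
                   list(kind = "categorical",
                        split = list(levels_left = left_lev)))
      }
    }
  }
  if (is.finite(best$gain)) best else NULL
}

grow_cart <- function(data, y, min_leaf, max_depth, depth, leaf_counter) {
  counts <- table(y)
  if (length(unique(y[!is.na(y)])) <= 1 || depth >= max_depth ||
      length(y) < 2 * min_leaf) {
    id <- leaf_counter()
    return(list(type = "leaf", id = id,
                label = names(counts)[which.max(counts)],
                counts = counts))
  }
  best <- NULL; best_var <- NULL
  for (v in names(data)) {
    cand <- best_split_var(data[[v]], y)
    if (!is.null(cand) && (is.null(best) || cand$gain > best$gain + 1e-12)) {
      best <- cand; best_var <- v
    }
  }
  ok_children <- function(go_left)
    sum(go_left) >= min_leaf && sum(!go_left) >= min_leaf
  if (!is.null(best)) {
    go_left <- if (best$kind == "numeric")
      data[[best_var]] < best$split$threshold
    else as.character(data[[best_var]]) %in% best$split$levels_left
    if (!ok_children(go_left)) best <- NULL
  }
  if (is.null(best)) {
    id <- leaf_counter()
    return(list(type = "leaf", id = id,
                label = names(counts)[which.max(counts)],
                counts = counts))
  }
  list(type = "split", var = best_var, kind = best$kind,
       split = best$split, gain = best$gain,
       left = grow_cart(data[go_left, , drop = FALSE], droplevels(y[go_left]),
                        min_leaf, max_depth, depth + 1, leaf_counter),
       right = grow_cart(data[!go_left, , drop = FALSE],
                         droplevels(y[!go_left]),
                         min_leaf, max_depth, depth + 1, leaf_counter),
       describe = "")
}

#' Fit a classification tree (CART, Gini impurity)
#'
#' Greedy binary recursive partitioning over mixed numeric/categorical
#' predictors, choosing at each node the split with the largest decrease
#' in Gini impurity. Numeric candidates are midpoints between sorted
#' distinct values; categorical candidates are all proper subsets of the
#' observed levels (up to 8 levels). Growth stops at class purity,
#' `min_leaf` or `max_depth`. No cost-complexity pruning is applied: the
#' fitted structure is read as final. Ties are broken deterministically
#' by column order, then by the first (smallest) candidate split.
#'
#' @param data Data frame of predictors (numeric, factor or character
#'   columns).
#' @param y Class labels (factor or character).
#' @param min_leaf Minimum records per leaf (default 2).
#' @param max_depth Maximum tree depth (default 5).
#' @return A `decision_tree` with fitted leaf counts.
#' @examples
#' d <- data.frame(x = c(1, 2, 3, 10, 11, 12))
#' fit_cart(d, rep(c("a", "b"), each = 3))
#' @export
fit_cart <- function(data, y, min_leaf = 2, max_depth = 5) {
  stopifnot(is.data.frame(data), nrow(data) == length(y))
  y <- droplevels(as.factor(y))
  if (any(is.na(y))) stop("labels contain missing values")
  if (anyNA(data)) stop("predictors contain missing values")
  counter_env <- new.env()
  counter_env$i <- 0L
  leaf_counter <- function() {
    counter_env$i <- counter_env$i + 1L
    paste0("leaf_", counter_env$i)
  }
  root <- grow_cart(data, y, min_leaf, max_depth, 0L, leaf_counter)
  structure(list(root = root, classes = levels(y), fitted = TRUE),
            class = "decision_tree")
}

#' @export
predict.decision_tree <- function(object, newdata,
                                  type = c("class", "leaf"), ...) {
  type <- match.arg(type)
  routed <- route_tree(object, newdata)
  if (type == "class") routed$label else routed$leaf
}

tree_depth <- function(node) {
  if (node$type == "leaf") 0L
  else 1L + max(tree_depth(node$left), tree_depth(node$right))
}
tree_n_leaves <- function(node) {
  if (node$type == "leaf") 1L
  else tree_n_leaves(node$left) + tree_n_leaves(node$right)
}

print_node <- function(node, indent = "") {
  if (node$type == "leaf") {
    cnt <- if (!is.null(node$counts))
      paste0(" [", paste(sprintf("%s:%d", names(node$counts),
                                 as.integer(node$counts)), collapse = " "), "]")
    else ""
    cat(indent, "* ", node$id, " -> ", node$label, cnt, "\n", sep = "")
  } else {
    lab <- if (node$kind == "numeric")
      sprintf("%s < %g", node$var, node$split$threshold)
    else sprintf("%s in {%s}", node$var,
                 paste(node$split$levels_left, collapse = ","))
    cat(indent, lab, "\n", sep = "")
    print_node(node$left, paste0(indent, "  "))
    cat(indent, "else\n", sep = "")
    print_node(node$right, paste0(indent, "  "))
  }
}

#' @export
print.decision_tree <- function(x, ...) {
  cat(sprintf("decision_tree (%s): %d leaves, depth %d, classes: %s\n",
              if (x$fitted) "fitted" else "fixed published structure",
              tree_n_leaves(x$root), tree_depth(x$root),
              paste(x$classes, collapse = ", ")))
  print_node(x$root)
  invisible(x)
}

#' @export
summary.decision_tree <- function(object, ...) {
  cat(sprintf("%d leaves, depth %d\n", tree_n_leaves(object$root),
              tree_depth(object$root)))
  invisible(object)
}

#' Export a decision tree as a nested list
#'
#' Structured export of a tree (fitted or the fixed published one) as a
#' plain nested list, directly serializable with `jsonlite::toJSON()`;
#' the `print()` method provides the human-readable indented form.
#'
#' @param tree A `decision_tree`.
#' @return A nested list of split and leaf nodes.
#' @export
tree_to_list <- function(tree) {
  strip <- function(node) {
    if (node$type == "leaf")
      list(type = "leaf", id = node$id, label = node$label,
           counts = if (!is.null(node$counts)) as.list(node$counts))
    else list(type = "split", var = node$var, kind = node$kind,
              split = node$split, left = strip(node$left),
              right = strip(node$right))
  }
  strip(tree$root)
}

#' Feature encoding of tooth records for classification
#'
#' Extracts the predictor columns used by the etiology tree from a
#' `tooth_records` table, dropping excluded teeth by default.
#'
#' @param records A `tooth_records` data frame.
#' @param drop_excluded Drop teeth flagged `excluded` (default TRUE).
#' @return Data frame with `tooth_id`, `etiology`, `pref`, `ant`,
#'   `max_thi_um`, `max_ve_um`, `wear_deg`.
#' @export
tree_features <- function(records, drop_excluded = TRUE) {
  d <- records[, c("tooth_id", "etiology", "pref", "ant", "max_thi_um",
                   "max_ve_um", "wear_deg")]
  if (drop_excluded) d <- d[!records$excluded, ]
  d$pref <- factor(as.integer(d$pref), levels = 0:1)
  d
}
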