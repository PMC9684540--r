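# Stability classification: a named feature registry computed from backbone
# plus sequence, a Gini-criterion bootstrap forest with out-of-bag and k-fold
# evaluation, rank-based ROC/AUC, and leave-one-fold-out ("dropout")
# generalisation tests.

#' Gini impurity index
#'
#' One minus the sum of squared class probabilities: 0 for a pure node,
#' maximal (1 - 1/n) at the uniform distribution over n classes.
#'
#' @param p vector of class probabilities (non-negative, summing to 1).
#' @return the impurity value.
#' @export
gini_index <- function(p) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("class probabilities must be non-negative and sum to 1")
  1 - sum(p^2)
}

#' The default stability feature registry
#'
#' A representative, extensible set of sequence- and structure-based
#' features: local-geometry fragment agreement (mean CA RMSD of 9-residue
#' windows rebuilt from the design's torsions against fragments rebuilt from
#' ideal secondary-structure torsions), buried-hydrophobic count, residue
#' contact-network degrees (mean and max), the hub-residue burial proxy
#' (contact-degree-weighted burial of the most connected residue), net
#' charge, chain length, secondary-structure fractions and related
#' composition terms.  Users extend the registry by appending named
#' functions of `(chain, sequence, ctx)`.
#'
#' @return named list of feature functions.
#' @export
default_feature_registry <- function() {
  list(
    frag_rmsd9 = function(chain, sequence, ctx) fragment_agreement_rmsd(chain),
    buried_hydrophobic = function(chain, sequence, ctx)
      sum(ctx$layers$layer == "core" & ctx$aa %in% .hydrophobic),
    core_count = function(chain, sequence, ctx) sum(ctx$layers$layer == "core"),
    mean_degree = function(chain, sequence, ctx) mean(ctx$degree),
    max_degree = function(chain, sequence, ctx) max(ctx$degree),
    hub_burial = function(chain, sequence, ctx) {
      hub <- which.max(ctx$degree)  # ties -> lowest index
      ctx$degree[hub] * ctx$layers$burial[hub]
    },
    net_charge = function(chain, sequence, ctx)
      sum(ctx$aa %in% c("K", "R")) - sum(ctx$aa %in% c("D", "E")),
    length = function(chain, sequence, ctx) chain$n,
    frac_helix = function(chain, sequence, ctx) mean(ctx$ss == "H"),
    frac_strand = function(chain, sequence, ctx) mean(ctx$ss == "E"),
    frac_loop = function(chain, sequence, ctx) mean(ctx$ss == "L"),
    hydrophobic_fraction = function(chain, sequence, ctx)
      mean(ctx$aa %in% .hydrophobic),
    mean_burial = function(chain, sequence, ctx) mean(ctx$layers$burial),
    n_contacts = function(chain, sequence, ctx) sum(ctx$degree) / 2,
    radius_gyration = function(chain, sequence, ctx) {
      ca <- ca_coords(chain)
      sqrt(mean(rowSums(sweep(ca, 2, colMeans(ca))^2)))
    }
  )
}

# mean CA RMSD of 9-residue windows rebuilt from measured torsions vs the
# same windows rebuilt from ideal secondary-structure torsions
fragment_agreement_rmsd <- function(chain, window = 9) {
  n <- chain$n
  if (n < window + 2) return(NA_real_)
  tor <- measure_torsions(chain)$torsions
  ss <- chain$ss %||% {
    ab <- strsplit(abego_string(chain), "")[[1]]
    ifelse(ab == "A", "H", ifelse(ab %in% c("B", "E"), "E", "L"))
  }
  ideal <- matrix(NA_real_, n, 3)
  ideal[ss == "H", 1] <- -57; ideal[ss == "H", 2] <- -47
  ideal[ss == "E", 1] <- -135; ideal[ss == "E", 2] <- 135
  ideal[, 3] <- 180
  loops <- ss == "L"
  ideal[loops, ] <- tor[loops, ]  # loops compared against themselves
  vals <- c()
  for (s in seq(2, n - window)) {
    idx <- s:(s + window - 1)
    ta <- tor[idx, , drop = FALSE]
    tb <- ideal[idx, , drop = FALSE]
    if (any(!is.finite(ta)) || any(!is.finite(tb))) next
    A <- ca_coords(torsions_to_coords(ta))
    B <- ca_coords(torsions_to_coords(tb))
    vals <- c(vals, superpose_rmsd(A, B)$rmsd)
  }
  if (!length(vals)) NA_real_ else mean(vals)
}

#' Extract a named feature vector for one design
#'
#' Contacts are CA pairs closer than 8 Angstrom with sequence separation of
#' at least 2; the hub residue is the most connected one (ties broken toward
#' the lowest index).  Values are keyed by registry name, so permuting the
#' registry permutes values under their names without changing them.
#'
#' @param chain a `backbone_chain`.
#' @param sequence one-letter amino-acid sequence, same length as the chain.
#' @param registry named list of feature functions
#'   (default [default_feature_registry()]).
#' @return named numeric vector.
#' @export
extract_features <- function(chain, sequence, registry = default_feature_registry()) {
  aa <- strsplit(paste(sequence, collapse = ""), "")[[1]]
  if (length(aa) != chain$n) stop("sequence length (", length(aa),
                                  ") does not match chain length (", chain$n, ")")
  if (is.null(names(registry)) || any(!nzchar(names(registry))))
    stop("feature registry entries must be named")
  ca <- ca_coords(chain)
  dmat <- as.matrix(stats::dist(ca))
  contact <- dmat < 8 & abs(row(dmat) - col(dmat)) >= 2
  ctx <- list(aa = aa, degree = rowSums(contact),
              layers = assign_layers(chain),
              ss = chain$ss %||% {
                ab <- strsplit(abego_string(chain), "")[[1]]
                ifelse(ab == "A", "H", ifelse(ab %in% c("B", "E"), "E", "L"))
              })
  vals <- vapply(names(registry), function(nm) {
    v <- registry[[nm]](chain, sequence, ctx)
    if (!is.numeric(v) || length(v) != 1)
      stop("feature '", nm, "' did not return a single number")
    as.numeric(v)
  }, numeric(1))
  vals
}

#' Train the random-forest stability classifier
#'
#' A bootstrap ensemble of Gini-criterion decision trees (500 by default,
#' `sqrt(p)` features per split), with generalisation estimated from the
#' out-of-bag samples and by k-fold cross-validation.
#'
#' @param dataset data frame with columns `label` (0/1), optionally `id` and
#'   `fold`, and numeric feature columns.
#' @param n_trees number of trees.
#' @param k_cv folds for cross-validation (default 5).
#' @param seed RNG seed for bootstrap/CV reproducibility.
#' @return a `trained_forest` with the fitted ensemble, `oob_accuracy` and
#'   `cv_accuracy`.
#' @export
train_forest <- function(dataset, n_trees = 500, k_cv = 5, seed = 1) {
  feats <- feature_columns(dataset)
  y <- factor(dataset$label, levels = c(0, 1))
  if (length(unique(dataset$label)) < 2)
    stop("training requires both stable and unstable examples")
  x <- dataset[, feats, drop = FALSE]
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(x = x, y = y, ntree = n_trees,
                                   mtry = max(1, floor(sqrt(length(feats)))),
                                   replace = TRUE, keep.forest = TRUE)
  oob <- 1 - rf$err.rate[n_trees, "OOB"]
  # k-fold CV accuracy
  idx <- sample(rep_len(seq_len(k_cv), nrow(dataset)))
  cv_hits <- 0
  for (k in seq_len(k_cv)) {
    tr <- idx != k
    if (length(unique(dataset$label[tr])) < 2) next
    rfk <- randomForest::randomForest(x = x[tr, , drop = FALSE], y = y[tr],
                                      ntree = n_trees,
                                      mtry = max(1, floor(sqrt(length(feats)))))
    cv_hits <- cv_hits + sum(predict(rfk, x[!tr, , drop = FALSE]) == y[!tr])
  }
  structure(list(forest = rf, features = feats, n_trees = n_trees,
                 oob_accuracy = as.numeric(oob),
                 cv_accuracy = cv_hits / nrow(dataset), seed = seed),
            class = "trained_forest")
}

#' @export
print.trained_forest <- function(x, ...) {
  cat(sprintf("trained_forest: %d trees, %d features, OOB accuracy %.3f, CV accuracy %.3f\n",
              x$n_trees, length(x$features), x$oob_accuracy, x$cv_accuracy))
  invisible(x)
}

#' Predict stability probabilities
#' @param object a `trained_forest`.
#' @param newdata data frame holding the registry feature columns.
#' @param ... unused.
#' @return numeric vector of stable-class probabilities.
#' @export
predict.trained_forest <- function(object, newdata, ...) {
  as.numeric(predict(object$forest, newdata[, object$features, drop = FALSE],
                     type = "prob")[, "1"])
}

feature_columns <- function(dataset) {
  setdiff(names(dataset)[vapply(dataset, is.numeric, logical(1))],
          c("label", "id"))
}

#' Rank-based ROC AUC
#'
#' Computed from ranks with average-rank tie handling (equivalent to the
#' normalised Mann-Whitney U statistic).
#'
#' @param scores classifier scores (higher = more likely positive).
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`; `NA` when only one class is present.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Leave-one-fold-out (dropout) evaluation
#'
#' For every fold label, trains the forest on all other folds and scores the
#' held-out fold, reporting the AUC; the procedure is repeated `n_repeats`
#' times with fresh seeds and summarised as min/median/max per fold.  Also
#' reports the whole-set AUC (out-of-bag scores over all designs) and a
#' mixed-heldout AUC (a random stratified 20% spanning all folds).  Folds
#' with a single class are flagged and receive an `NA` AUC.
#'
#' @param dataset data frame as for [train_forest()], requiring a `fold`
#'   column.
#' @param n_trees trees per forest.
#' @param n_repeats training repetitions.
#' @param seed base RNG seed.
#' @return list with `per_fold` (data frame fold/min/median/max AUC),
#'   `whole_set_auc`, `mixed_auc`, and `degenerate` fold names.
#' @export
dropout_eval <- function(dataset, n_trees = 500, n_repeats = 3, seed = 1) {
  stopifnot("fold" %in% names(dataset))
  feats <- feature_columns(dataset)
  folds <- unique(as.character(dataset$fold))
  degenerate <- folds[vapply(folds, function(f)
    length(unique(dataset$label[dataset$fold == f])) < 2, logical(1))]
  if (length(degenerate))
    warning("fold(s) with a single stability class: ",
            paste(degenerate, collapse = ", "))
  aucs <- matrix(NA_real_, length(folds), n_repeats,
                 dimnames = list(folds, NULL))
  for (rep in seq_len(n_repeats)) {
    for (f in folds) {
      hold <- dataset$fold == f
      if (length(unique(dataset$label[!hold])) < 2 || f %in% degenerate) next
      fit <- train_forest(dataset[!hold, , drop = FALSE], n_trees = n_trees,
                          k_cv = 2, seed = seed + rep * 1000 + match(f, folds))
      sc <- predict(fit, dataset[hold, , drop = FALSE])
      aucs[f, rep] <- roc_auc(sc, dataset$label[hold])
    }
  }
  per_fold <- data.frame(fold = folds,
                         min = apply(aucs, 1, min),
                         median = apply(aucs, 1, stats::median),
                         max = apply(aucs, 1, max),
                         stringsAsFactors = FALSE)
  set.seed(as.integer(seed))
  whole <- train_forest(dataset, n_trees = n_trees, k_cv = 2, seed = seed)
  oob_scores <- as.numeric(predict(whole$forest, type = "prob")[, "1"])
  whole_auc <- roc_auc(oob_scores, dataset$label)
  hold <- unlist(lapply(split(seq_len(nrow(dataset)), dataset$fold),
                        function(ix) sample(ix, max(1, round(0.2 * length(ix))))))
  mixed_auc <- if (length(unique(dataset$label[-hold])) < 2) NA_real_ else {
    fit <- train_forest(dataset[-hold, , drop = FALSE], n_trees = n_trees,
                        k_cv = 2, seed = seed + 77)
    roc_auc(predict(fit, dataset[hold, , drop = FALSE]), dataset$label[hold])
  }
  list(per_fold = per_fold, whole_set_auc = whole_auc, mixed_auc = mixed_auc,
       degenerate = degenerate, aucs = aucs)
}

#' Simulate a multi-fold stability dataset
#'
#' Synthetic benchmark for the classifier: designs from several fold
#' families, each with fold-specific baseline feature shifts, where the
#' stable/unstable label depends (through a logistic model) only on
#' fold-independent features when `effect > 0`, or on nothing (pure noise)
#' when `effect = 0`.  Used to verify that dropout evaluation recovers
#' fold-transferable signal and collapses to chance on label-independent
#' features.
#'
#' @param n_per_fold designs per fold.
#' @param folds fold family names.
#' @param effect strength of the feature-label association (0 = labels are
#'   pure coin flips, independent of every feature).
#' @param noise `threshold` gives fully feature-determined (separable)
#'   labels; `logistic` adds Bernoulli label noise near the boundary.
#' @param n_features number of numeric features (>= 4).
#' @param seed RNG seed.
#' @return data frame with `id`, `fold`, `label` and feature columns.
#' @export
simulate_stability_dataset <- function(n_per_fold = 60,
                                       folds = c("3H", "bbab", "ferredoxin", "betagrasp"),
                                       effect = 3, noise = c("threshold", "logistic"),
                                       n_features = 8, seed = 1) {
  stopifnot(n_features >= 4)
  noise <- match.arg(noise)
  set.seed(as.integer(seed))
  n <- n_per_fold * length(folds)
  fold <- rep(folds, each = n_per_fold)
  x <- matrix(rnorm(n * n_features), n, n_features,
              dimnames = list(NULL, paste0("f", seq_len(n_features))))
  # fold-specific shifts on the last two features only (nuisance structure)
  for (k in seq_along(folds)) {
    rows <- fold == folds[k]
    x[rows, n_features - 1] <- x[rows, n_features - 1] + k
    x[rows, n_features] <- x[rows, n_features] - k / 2
  }
  lin <- effect * (0.8 * x[, 1] - 0.6 * x[, 2] + 0.4 * x[, 3])
  label <- if (effect == 0) stats::rbinom(n, 1, 0.5)
           else if (noise == "threshold") as.integer(lin > 0)
           else stats::rbinom(n, 1, stats::plogis(lin))
  data.frame(id = sprintf("d%04d", seq_len(n)), fold = fold, label = label,
             x, stringsAsFactors = FALSE)
}
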