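# Virtual-screening evaluation: ranking AUC, enrichment factors and
# leave-one-target-out experiment scaffolding.

#' Construct a screening result
#'
#' A scored, labelled compound ranking; scores rank descending (higher =
#' more active-like).
#'
#' @param compound_id character vector.
#' @param target_id character vector (recycled).
#' @param score numeric scores.
#' @param label `"active"`/`"decoy"` character vector, or logical/0-1
#'   (TRUE/1 = active).
#' @return object of class `ScreenResult` (a data frame).
#' @export
screen_result <- function(compound_id, target_id, score, label) {
  if (is.logical(label) || is.numeric(label))
    label <- ifelse(as.logical(label), "active", "decoy")
  if (!all(label %in% c("active", "decoy")))
    stop("labels must be active/decoy")
  out <- data.frame(compound_id = as.character(compound_id),
                    target_id = rep_len(as.character(target_id),
                                        length(compound_id)),
                    score = as.numeric(score), label = label,
                    stringsAsFactors = FALSE)
  class(out) <- c("ScreenResult", "data.frame")
  out
}

#' Screening AUC
#'
#' `AUC = 1 - (1/N_a) * sum_i N_d^i / N_d`, where `N_d^i` is the number of
#' decoys ranked above the i-th active; decoys tied with an active count
#' one half.  1 is a perfect ranking, 0.5 the expectation under random
#' scoring.
#'
#' @param sr a [screen_result()].
#' @return value in \[0, 1\].
#' @export
auc <- function(sr) {
  act <- sr$score[sr$label == "active"]
  dec <- sr$score[sr$label == "decoy"]
  if (length(act) == 0 || length(dec) == 0)
    stop("need at least one active and one decoy")
  above <- vapply(act, function(s)
    sum(dec > s) + 0.5 * sum(dec == s), numeric(1))
  1 - mean(above) / length(dec)
}

#' Enrichment factor at x percent
#'
#' `EF = (N_a^x / N^x) * (N / N_a)` with `N^x = ceiling(x N / 100)` top
#' ranked compounds: the active fraction among the top x% relative to the
#' overall active fraction.
#'
#' @param sr a [screen_result()].
#' @param x percentage in (0, 100].
#' @return the enrichment factor.
#' @export
enrichment_factor <- function(sr, x) {
  if (nrow(sr) == 0) stop("empty ranking")
  if (x <= 0 || x > 100) stop("x must be in (0, 100]")
  n <- nrow(sr)
  na <- sum(sr$label == "active")
  if (na == 0) stop("need at least one active")
  ntop <- ceiling(x * n / 100)
  ord <- order(-sr$score)
  natop <- sum(sr$label[ord[seq_len(ntop)]] == "active")
  (natop / ntop) * (n / na)
}

#' Leave-one-target-out screening experiment
#'
#' For each target, trains the voting classifier ensemble on the entries of
#' all other targets (minus any configured exclusions) and scores the
#' held-out target, reporting per-target AUC and enrichment factors plus
#' their unweighted averages.
#'
#' @param features numeric feature matrix, one row per compound entry.
#' @param labels 0/1 or `"active"`/`"decoy"` labels per row.
#' @param targets target id per row.
#' @param exclusions named list: target id -> character vector of target
#'   ids to drop from its training set.
#' @param seed integer seed for the learners.
#' @param n_estimators tree-count override passed to the voters.
#' @param ef_percent enrichment-factor levels to report.
#' @return data frame with one row per target plus an `"average"` row,
#'   columns `target`, `auc` and one `ef<level>` column per level; per-
#'   compound scores are attached as attribute `"scores"`.
#' @export
leave_one_target_out <- function(features, labels, targets,
                                 exclusions = list(), seed = 1,
                                 n_estimators = NULL,
                                 ef_percent = c(2, 20)) {
  features <- as.matrix(features)
  if (is.character(labels)) labels <- as.integer(labels == "active")
  labels <- as.integer(labels)
  targets <- as.character(targets)
  tids <- unique(targets)
  if (length(bad <- setdiff(names(exclusions), tids)) > 0)
    stop("exclusion map names unknown target(s): ",
         paste(bad, collapse = ", "))
  rows <- list()
  scores <- data.frame()
  for (t in tids) {
    test <- targets == t
    drop <- c(t, exclusions[[t]])
    train <- !(targets %in% drop)
    if (!any(train)) stop("no training entries left for target ", t)
    prob <- screen_voters_predict(features[train, , drop = FALSE],
                                  labels[train],
                                  features[test, , drop = FALSE],
                                  seed = seed,
                                  n_estimators = n_estimators)
    sr <- screen_result(which(test), t, prob, labels[test])
    row <- data.frame(target = t, auc = auc(sr))
    for (x in ef_percent)
      row[[paste0("ef", x)]] <- enrichment_factor(sr, x)
    rows[[t]] <- row
    scores <- rbind(scores, sr)
  }
  out <- do.call(rbind, rows)
  avg <- data.frame(target = "average", auc = mean(out$auc))
  for (x in ef_percent) {
    cn <- paste0("ef", x)
    avg[[cn]] <- mean(out[[cn]])
  }
  out <- rbind(out, avg)
  rownames(out) <- NULL
  attr(out, "scores") <- scores
  out
}

#' Write a screening result or report to CSV
#'
#' @param x a `ScreenResult` or report data frame.
#' @param path output path.
#' @export
write_screen_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' End-to-end screening experiment on a synthetic screen set
#'
#' Featurizes every complex of a [make_screen_set()] with the given feature
#' groups and runs the leave-one-target-out voting-classifier experiment.
#'
#' @param screen_set output of [make_screen_set()].
#' @param groups feature-group ids (default the 36-pair interactive
#'   dim-0 counts).
#' @param seed integer seed.
#' @param n_estimators tree-count override for the voters.
#' @return the [leave_one_target_out()] report.
#' @export
run_screen_experiment <- function(screen_set, groups = "R-B0-I-BP",
                                  seed = 1, n_estimators = 500) {
  feats <- topo_feature_matrix(screen_set$complexes, groups)
  leave_one_target_out(feats, screen_set$labels, screen_set$targets,
                       seed = seed, n_estimators = n_estimators)
}
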