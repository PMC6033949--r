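#' The published non-essentiality model
#'
#' The logistic model mapping standardized per-gene features to a
#' non-essentiality probability (NEP),
#' \deqn{y = \frac{1}{1 + e^{-(5.737 x_1 + 0.082 x_2 + 2.098)}}}
#' where \eqn{x_1} is the standardized Gene Insertion Index and \eqn{x_2}
#' the standardized read density. The coefficients ship as a built-in so
#' genomes can be classified without retraining. The standardization
#' parameters behind the published fit were not released, so they must be
#' supplied (typically from the user's own labelled training set) before
#' this model can be applied to raw GII / read-density values; without
#' them, `predict()` expects already-standardized features.
#'
#' @param feature_means,feature_sds Optional numeric vectors of length 2
#'   (names `gii`, `read_density`) used to standardize raw features.
#' @return A `nep_model` object.
#' @export
published_nep_model <- function(feature_means = NULL, feature_sds = NULL) {
  if (!is.null(feature_sds) && any(feature_sds <= 0)) {
    stop("feature_sds must be positive")
  }
  structure(list(beta_gii = 5.737, beta_density = 0.082, intercept = 2.098,
                 feature_means = feature_means, feature_sds = feature_sds,
                 published = TRUE, accuracy = NULL, C = NA_real_),
            class = "nep_model")
}

# L2-penalized logistic regression via Newton-IRLS.
# Objective: (1/n) sum(log-loss) + lambda/2 * ||beta||^2 (intercept
# unpenalized), with lambda = 1/(C*n) -- the parameterization in which C
# plays its usual inverse-regularization-strength role.
.fit_penalized_logistic <- function(X, y, C = 10, max_iter = 100L,
                                    tol = 1e-10) {
  n <- nrow(X)
  lambda <- 1 / (C * n)
  Xd <- cbind(1, X)
  p <- ncol(Xd)
  R <- diag(c(0, rep(lambda, p - 1L)))
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(Xd, mu - y)) / n + drop(R %*% beta)
    W <- mu * (1 - mu)
    H <- crossprod(Xd * W, Xd) / n + R
    step <- tryCatch(solve(H, grad),
                     error = function(e) stop("logistic fit failed: singular ",
                                              "Hessian (", conditionMessage(e),
                                              ")", call. = FALSE))
    beta <- beta - step
    if (max(abs(step)) < tol) {
      return(list(beta = beta, iterations = it, converged = TRUE))
    }
  }
  stop("logistic fit did not converge in ", max_iter,
       " iterations (max |step| = ", signif(max(abs(step)), 3), ")")
}

# stratified split: indices of the test set, sizes allocated per class by
# largest-remainder rounding of class_size * test_fraction
.stratified_test_idx <- function(y, test_fraction) {
  n_test <- round(length(y) * test_fraction)
  classes <- sort(unique(y))
  ideal <- vapply(classes, function(cl) sum(y == cl) * test_fraction,
                  numeric(1))
  base <- floor(ideal)
  extra <- n_test - sum(base)
  if (extra > 0) {
    give <- order(ideal - base, decreasing = TRUE)[seq_len(extra)]
    base[give] <- base[give] + 1L
  }
  idx <- integer(0)
  for (i in seq_along(classes)) {
    members <- which(y == classes[i])
    idx <- c(idx, sample(members, base[i]))
  }
  sort(idx)
}

#' Fit the non-essentiality logistic model from labelled genes
#'
#' Standardizes the two features (GII, read density) using the labelled
#' set's means and standard deviations, evaluates held-out accuracy over
#' repeated stratified train/test splits, and refits the final model on
#' all labelled data. The fit is L2-regularized logistic regression
#' (regularization strength `1/C`, intercept unpenalized) solved by
#' Newton iteration on the penalized likelihood.
#'
#' @param stats Per-gene statistics from [compute_gene_stats()].
#' @param labels `data.frame` with columns `gene_id` and `label`
#'   (`"essential"` / `"non_essential"`); non-essential is the positive
#'   class (NEP close to 1).
#' @param C Inverse regularization strength (default 10).
#' @param test_fraction Held-out fraction per repeat (default 0.30).
#' @param repeats Number of random splits (default 10); repeat `r` uses
#'   seed `seed + r - 1`.
#' @param seed Base RNG seed.
#' @return A `nep_model` with coefficients `beta_gii`, `beta_density`,
#'   `intercept`, the standardization parameters, and per-repeat held-out
#'   `accuracy`.
#' @export
fit_nep_model <- function(stats, labels, C = 10, test_fraction = 0.30,
                          repeats = 10L, seed = 1L) {
  if (!all(c("gene_id", "label") %in% names(labels))) {
    stop("labels must have columns gene_id, label")
  }
  if (!all(labels$label %in% c("essential", "non_essential"))) {
    stop("labels must be 'essential' or 'non_essential'")
  }
  m <- merge(labels, stats[, c("gene_id", "gii", "read_density")],
             by = "gene_id")
  missing <- setdiff(labels$gene_id, m$gene_id)
  if (length(missing) > 0L) {
    stop("labelled gene(s) absent from stats: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  m <- m[stats::complete.cases(m[, c("gii", "read_density")]), , drop = FALSE]
  if (length(unique(m$label)) < 2L) stop("both classes must be present")
  if (nrow(m) < 10L) stop("need at least 10 labelled genes")

  y <- as.integer(m$label == "non_essential")
  feats <- as.matrix(m[, c("gii", "read_density")])
  mu <- colMeans(feats)
  sdv <- apply(feats, 2L, stats::sd)
  if (any(sdv == 0)) {
    stop("zero standard deviation in feature: ",
         paste(names(sdv)[sdv == 0], collapse = ", "))
  }
  X <- scale(feats, center = mu, scale = sdv)

  accuracy <- numeric(repeats)
  for (r in seq_len(repeats)) {
    set.seed(seed + r - 1L)
    test <- .stratified_test_idx(y, test_fraction)
    fit <- .fit_penalized_logistic(X[-test, , drop = FALSE], y[-test], C = C)
    eta <- drop(cbind(1, X[test, , drop = FALSE]) %*% fit$beta)
    accuracy[r] <- mean(as.integer(eta > 0) == y[test])
  }
  final <- .fit_penalized_logistic(X, y, C = C)

  structure(list(beta_gii = unname(final$beta[2]),
                 beta_density = unname(final$beta[3]),
                 intercept = unname(final$beta[1]),
                 feature_means = stats::setNames(mu, c("gii", "read_density")),
                 feature_sds = stats::setNames(sdv, c("gii", "read_density")),
                 published = FALSE, accuracy = accuracy, C = C,
                 n_labelled = nrow(m),
                 class_counts = table(m$label)),
            class = "nep_model")
}

#' Standardize per-gene features with a model's training parameters
#'
#' @param stats Table from [compute_gene_stats()].
#' @param model A `nep_model` carrying `feature_means` / `feature_sds`.
#' @return `data.frame` with `gene_id`, `x1` (standardized GII), `x2`
#'   (standardized read density).
#' @export
standardize_features <- function(stats, model) {
  if (is.null(model$feature_means) || is.null(model$feature_sds)) {
    stop("model carries no standardization parameters; supply feature_means/",
         "feature_sds (e.g. from a labelled training set)")
  }
  if (any(model$feature_sds <= 0)) {
    stop("zero/negative sd for feature: ",
         paste(names(model$feature_sds)[model$feature_sds <= 0],
               collapse = ", "))
  }
  data.frame(
    gene_id = stats$gene_id,
    x1 = (stats$gii - model$feature_means[["gii"]]) /
      model$feature_sds[["gii"]],
    x2 = (stats$read_density - model$feature_means[["read_density"]]) /
      model$feature_sds[["read_density"]],
    stringsAsFactors = FALSE)
}

#' Non-essentiality probability
#'
#' Evaluates the logistic model on standardized features:
#' `1 / (1 + exp(-(beta_gii * x1 + beta_density * x2 + intercept)))`.
#' Strictly increasing in each feature for positive coefficients;
#' saturates numerically at 0/1 for extreme inputs.
#'
#' @param model A `nep_model`.
#' @param x1 Standardized GII value(s).
#' @param x2 Standardized read-density value(s).
#' @return Probability vector in `[0, 1]`.
#' @export
nep <- function(model, x1, x2) {
  z <- model$beta_gii * x1 + model$beta_density * x2 + model$intercept
  1 / (1 + exp(-z))
}

#' @export
coef.nep_model <- function(object, ...) {
  c(intercept = object$intercept, beta_gii = object$beta_gii,
    beta_density = object$beta_density)
}

#' Predict non-essentiality from per-gene statistics
#'
#' @param object A `nep_model`.
#' @param newdata Either a stats table from [compute_gene_stats()] (raw
#'   `gii` / `read_density`, standardized internally with the model's
#'   training parameters) or a `data.frame` with columns `x1`, `x2`
#'   already standardized.
#' @param type `"nep"` (probability), `"link"` (linear predictor) or
#'   `"class"` (`"non_essential"` when NEP > 0.5).
#' @param ... Unused.
#' @return Numeric (or character for `type = "class"`) vector, named by
#'   `gene_id` when available.
#' @export
predict.nep_model <- function(object, newdata,
                              type = c("nep", "link", "class"), ...) {
  type <- match.arg(type)
  if (all(c("x1", "x2") %in% names(newdata))) {
    x1 <- newdata$x1; x2 <- newdata$x2
  } else {
    std <- standardize_features(newdata, object)
    x1 <- std$x1; x2 <- std$x2
  }
  z <- object$beta_gii * x1 + object$beta_density * x2 + object$intercept
  out <- switch(type,
                link = z,
                nep = 1 / (1 + exp(-z)),
                class = ifelse(z > 0, "non_essential", "essential"))
  if (!is.null(newdata$gene_id)) names(out) <- newdata$gene_id
  out
}

#' @export
print.nep_model <- function(x, ...) {
  cat(if (isTRUE(x$published)) "Published" else "Fitted",
      "non-essentiality logistic model\n")
  cat(sprintf("  NEP = 1 / (1 + exp(-(%.3f*x1 + %.3f*x2 + %.3f)))\n",
              x$beta_gii, x$beta_density, x$intercept))
  if (!is.null(x$accuracy)) {
    cat(sprintf("  held-out accuracy: mean %.3f (sd %.3f) over %d splits\n",
                mean(x$accuracy), stats::sd(x$accuracy), length(x$accuracy)))
  }
  if (is.null(x$feature_means)) {
    cat("  (no standardization parameters: expects standardized features)\n")
  }
  invisible(x)
}

#' @export
summary.nep_model <- function(object, ...) {
  print(object)
  if (!is.null(object$feature_means)) {
    cat("  feature standardization:\n")
    cat(sprintf("    gii:          mean %.4f, sd %.4f\n",
                object$feature_means[["gii"]], object$feature_sds[["gii"]]))
    cat(sprintf("    read_density: mean %.4f, sd %.4f\n",
                object$feature_means[["read_density"]],
                object$feature_sds[["read_density"]]))
  }
  if (!is.null(object$class_counts)) {
    cat("  training labels: ",
        paste(names(object$class_counts), object$class_counts,
              sep = " = ", collapse = ", "), "\n", sep = "")
  }
  invisible(object)
}

#' Classify genes into essentiality categories
#'
#' Applies a fitted/published model genome-wide and assigns the four
#' categories from the NEP thresholds `(t1, t2, t3)` (defaults 0.03, 0.5,
#' 0.9): putatively essential when `nep < t1`, `ambig1` when
#' `t1 <= nep < t2`, `ambig2` when `t2 <= nep <= t3`, putatively
#' non-essential when `nep > t3`. Genes with fewer than `min_ta` TA sites
#' (unreliable features), genes named in `marker_genes` (the transposon's
#' selection marker attracts spurious insertions), and genes with
#' undefined features are excluded with a reason.
#'
#' @param stats Table from [compute_gene_stats()].
#' @param model A `nep_model`.
#' @param thresholds Strictly increasing NEP cutpoints within (0, 1).
#' @param min_ta Minimum full-gene TA count (default 15).
#' @param marker_genes Gene ids to exclude as selection markers.
#' @return `data.frame` of class `essentiality_records`: `gene_id`, `gii`,
#'   `read_density`, `x1`, `x2`, `nep`, `category`, `exclusion_reason`;
#'   category counts in attribute `summary`.
#' @export
classify_essentiality <- function(stats, model,
                                  thresholds = c(0.03, 0.5, 0.9),
                                  min_ta = 15L,
                                  marker_genes = character()) {
  if (length(thresholds) != 3L || any(diff(thresholds) <= 0) ||
      thresholds[1] <= 0 || thresholds[3] >= 1) {
    stop("thresholds must be three strictly increasing values in (0, 1)")
  }
  excl <- rep("none", nrow(stats))
  excl[stats$ta_full < min_ta] <- "low_ta"
  excl[!stats$defined] <- "undefined_features"
  excl[stats$gene_id %in% marker_genes] <- "marker_gene"
  usable <- excl == "none"

  x1 <- x2 <- p <- rep(NA_real_, nrow(stats))
  if (any(usable)) {
    std <- standardize_features(stats[usable, , drop = FALSE], model)
    x1[usable] <- std$x1
    x2[usable] <- std$x2
    p[usable] <- nep(model, std$x1, std$x2)
  }

  category <- rep("excluded", nrow(stats))
  category[usable & p < thresholds[1]] <- "putatively_essential"
  category[usable & p >= thresholds[1] & p < thresholds[2]] <- "ambig1"
  category[usable & p >= thresholds[2] & p <= thresholds[3]] <- "ambig2"
  category[usable & p > thresholds[3]] <- "putatively_non_essential"

  out <- data.frame(gene_id = stats$gene_id, gii = stats$gii,
                    read_density = stats$read_density,
                    x1 = x1, x2 = x2, nep = p,
                    category = factor(category,
                                      levels = c("putatively_essential",
                                                 "ambig1", "ambig2",
                                                 "putatively_non_essential",
                                                 "excluded")),
                    exclusion_reason = excl,
                    stringsAsFactors = FALSE)
  attr(out, "summary") <- table(out$category)
  class(out) <- c("essentiality_records", "data.frame")
  out
}

#' Cross-tabulate predicted categories against known labels
#'
#' @param records An `essentiality_records` table from
#'   [classify_essentiality()].
#' @param labels `data.frame` with `gene_id`, `label`.
#' @return List with `table` (label x category counts), `n_matched`, and
#'   `error_rate`: the fraction of known non-essential genes classified
#'   putatively essential plus known essential genes classified putatively
#'   non-essential (the confident misassignments).
#' @export
validate_against_labels <- function(records, labels) {
  m <- merge(labels, records[, c("gene_id", "category")], by = "gene_id")
  if (nrow(m) == 0L) {
    return(list(table = table(character(0), character(0)),
                n_matched = 0L, error_rate = NA_real_))
  }
  tab <- table(label = m$label, category = m$category)
  bad <- sum(m$label == "non_essential" &
               m$category == "putatively_essential") +
    sum(m$label == "essential" & m$category == "putatively_non_essential")
  list(table = tab, n_matched = nrow(m), error_rate = bad / nrow(m))
}

#' Read a gene-label table
#'
#' @param path TSV with columns `gene_id`, `label`.
#' @return `data.frame` with validated labels.
#' @export
read_labels_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("gene_id", "label") %in% names(df))) {
    stop("label file must have columns gene_id, label")
  }
  if (!all(df$label %in% c("essential", "non_essential"))) {
    stop("labels must be 'essential' or 'non_essential'")
  }
  df
}

#' Save / load a model as JSON
#'
#' @param model A `nep_model`.
#' @param path JSON file path.
#' @return `write_nep_model()`: `path` invisibly; `read_nep_model()`: a
#'   `nep_model`.
#' @export
write_nep_model <- function(model, path) {
  obj <- list(beta_gii = model$beta_gii, beta_density = model$beta_density,
              intercept = model$intercept,
              feature_means = as.list(model$feature_means),
              feature_sds = as.list(model$feature_sds),
              published = isTRUE(model$published),
              accuracy = model$accuracy, C = model$C)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_nep_model
#' @export
read_nep_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fm <- if (length(obj$feature_means)) unlist(obj$feature_means) else NULL
  fs <- if (length(obj$feature_sds)) unlist(obj$feature_sds) else NULL
  structure(list(beta_gii = obj$beta_gii, beta_density = obj$beta_density,
                 intercept = obj$intercept,
                 feature_means = fm, feature_sds = fs,
                 published = isTRUE(obj$published),
                 accuracy = obj$accuracy,
                 C = if (is.null(obj$C)) NA_real_ else obj$C),
            class = "nep_model")
}

#' Write classification records as TSV
#'
#' @param records `essentiality_records` from [classify_essentiality()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_classification <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_classification
#' @export
read_classification <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$category <- factor(df$category,
                        levels = c("putatively_essential", "ambig1", "ambig2",
                                   "putatively_non_essential", "excluded"))
  class(df) <- c("essentiality_records", "data.frame")
  df
}
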