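# The sperm methylation age predictor: EWAS-ranked feature selection,
# elastic-net fitting with LOOCV lambda tuning, nested LOOCV evaluation,
# prediction and plain-text model serialization.

#' Select clock CpGs from EWAS results
#'
#' Ranks all estimable sites by ascending p (ties broken by descending
#' |effect|, then by chromosome and position, making the ranking fully
#' deterministic), takes the top `k`, then drops any site with a missing
#' methylation value in any sample — the clock trains only on CpGs
#' measured in every donor. Order is preserved.
#'
#' @param results [runEwas()] output.
#' @param me the [MethylationExperiment-class] the results came from.
#' @param k number of top-ranked sites to start from (default 5000).
#' @return character vector of site ids.
#' @export
selectClockCpgs <- function(results, me, k = 5000L) {
  r <- results[results$estimable & !is.na(results$p), , drop = FALSE]
  o <- order(r$p, -abs(r$effect), r$chrom, r$pos)
  top <- r$id[o][seq_len(min(k, nrow(r)))]
  beta <- betaValues(me)
  complete <- rownames(beta)[rowSums(is.na(beta)) == 0]
  sel <- top[top %in% complete]
  if (length(sel) < 2L)
    stop("fewer than 2 clock CpGs survive the completeness rule")
  sel
}

# shared lambda path: nlambda log-spaced values from the data-driven
# maximal lambda down to lambda_min_ratio of it (built explicitly, since
# glmnet's own path can stop early once the deviance plateaus)
.lambdaGrid <- function(X, y, alpha, nlambda, lambda_min_ratio) {
  fit <- glmnet::glmnet(X, y, alpha = alpha, nlambda = 3L,
                        standardize = TRUE)
  lmax <- max(fit$lambda)
  exp(seq(log(lmax), log(lmax * lambda_min_ratio),
          length.out = nlambda))
}

.augmentSingle <- function(X) {
  # glmnet requires >= 2 columns; pad with a constant (coefficient 0)
  if (ncol(X) >= 2L) return(list(X = X, pad = FALSE))
  list(X = cbind(X, .pad. = 0), pad = TRUE)
}

#' Train the elastic-net methylation age clock
#'
#' Elastic-net linear regression of chronological age on methylation
#' proportions (glmnet, mixing parameter `alpha = 0.5` by default).
#' The penalty `lambda` minimizes leave-one-out cross-validated mean
#' squared error over a data-driven logarithmic grid (`nlambda` values
#' down to `lambda_min_ratio` of the maximal lambda). Features are
#' standardized internally; coefficients are reported on the original
#' proportion scale. Fully deterministic given the inputs and grid.
#'
#' @param beta_subset features x samples matrix of methylation
#'   proportions, no missing values (rownames are CpG ids).
#' @param ages per-sample ages in years.
#' @param alpha elastic-net mixing in `[0, 1]`.
#' @param nlambda,lambda_min_ratio lambda grid shape.
#' @return an [AgeClockModel-class].
#' @export
trainAgeClock <- function(beta_subset, ages, alpha = 0.5,
                          nlambda = 100L, lambda_min_ratio = 1e-4) {
  stopifnot(is.matrix(beta_subset), !anyNA(beta_subset))
  n <- length(ages)
  if (ncol(beta_subset) != n)
    stop("beta_subset must be features x samples matching ages")
  if (n < 10L) stop("need at least 10 training samples")
  if (sd(ages) == 0) stop("constant age vector: nothing to learn")
  X0 <- t(beta_subset)
  aug <- .augmentSingle(X0)
  X <- aug$X
  grid <- .lambdaGrid(X, ages, alpha, nlambda, lambda_min_ratio)
  cv <- glmnet::cv.glmnet(X, ages, alpha = alpha, lambda = grid,
                          foldid = seq_len(n), grouped = FALSE,
                          standardize = TRUE)
  lam <- cv$lambda.min
  fit <- glmnet::glmnet(X, ages, alpha = alpha, lambda = grid,
                        standardize = TRUE)
  cf <- as.numeric(coef(fit, s = lam))
  ids <- rownames(beta_subset)
  coefs <- cf[-1L]
  if (aug$pad) coefs <- coefs[-length(coefs)]
  new("AgeClockModel",
      cpg_ids = ids, intercept = cf[1L], coefficients = coefs,
      alpha = alpha, lambda = lam, lambda_grid = grid,
      training_n = as.integer(n),
      feature_selection = list(
        training_means = setNames(rowMeans(beta_subset), ids)))
}

#' Predict age from methylation
#'
#' `intercept + beta %*% coefficients`, no clamping — negative or
#' super-centenarian predictions are reported as-is. Every model CpG must
#' be present with non-missing beta in every sample; otherwise an error
#' lists the offending sites, unless `impute = TRUE`, which fills missing
#' values with the training means stored in the model.
#'
#' @param model an [AgeClockModel-class].
#' @param me a [MethylationExperiment-class] (or a features x samples beta
#'   matrix).
#' @param impute impute missing features with training means (off by
#'   default).
#' @return named numeric vector of predicted ages (years).
#' @export
predictAge <- function(model, me, impute = FALSE) {
  beta <- if (is.matrix(me)) me else betaValues(me)
  missing_sites <- setdiff(model@cpg_ids, rownames(beta))
  if (length(missing_sites) && !impute)
    stop("model CpGs absent from matrix: ",
         paste(head(missing_sites, 5), collapse = ", "),
         if (length(missing_sites) > 5) " ...")
  B <- matrix(NA_real_, length(model@cpg_ids), ncol(beta),
              dimnames = list(model@cpg_ids, colnames(beta)))
  present <- intersect(model@cpg_ids, rownames(beta))
  B[present, ] <- beta[present, , drop = FALSE]
  if (anyNA(B)) {
    if (!impute) {
      bad <- rownames(B)[rowSums(is.na(B)) > 0]
      stop("missing beta for model CpGs: ",
           paste(head(bad, 5), collapse = ", "),
           if (length(bad) > 5) " ...")
    }
    mu <- model@feature_selection$training_means[rownames(B)]
    for (i in which(rowSums(is.na(B)) > 0))
      B[i, is.na(B[i, ])] <- mu[i]
  }
  as.numeric(model@intercept + crossprod(B, model@coefficients))[
    seq_len(ncol(B))] |> setNames(colnames(B))
}

#' Leave-one-out evaluation of the age clock
#'
#' Outer LOOCV: for each donor, the EWAS ranking, top-`k` feature
#' selection and inner LOOCV lambda tuning are all refit on the remaining
#' n-1 donors only (no selection leakage), and the held-out donor's age is
#' predicted. `fixed_selection = TRUE` instead selects features once on
#' the full cohort — the optimistic variant, reported for comparison only.
#' The returned deployable model is trained once on all samples.
#'
#' @param me a filtered [MethylationExperiment-class].
#' @param sheet sample sheet (defaults to `sampleSheet(me)`).
#' @param ewas_fn function `(me, sheet) -> runEwas()-style data.frame`
#'   used for per-fold ranking; the default runs an unadjusted age EWAS.
#' @param k,alpha,nlambda,lambda_min_ratio passed to [selectClockCpgs()] /
#'   [trainAgeClock()].
#' @param fixed_selection reuse a single full-data feature selection in
#'   every fold (leaky; off by default).
#' @return list: `evaluation` (`data.frame` sample, true age, predicted,
#'   abs_error), `mae` (mean absolute error, years), `n`, `model` (the
#'   full-data [AgeClockModel-class]), `fixed_selection` flag.
#' @export
loocvEvaluate <- function(me, sheet = NULL, ewas_fn = NULL, k = 5000L,
                          alpha = 0.5, nlambda = 100L,
                          lambda_min_ratio = 1e-4,
                          fixed_selection = FALSE) {
  if (is.null(sheet)) sheet <- sampleSheet(me)
  n <- ncol(me)
  if (n < 10L) stop("need at least 10 samples for LOOCV")
  ages <- as.numeric(sheet$age)
  if (is.null(ewas_fn))
    ewas_fn <- function(m, s) runEwas(m, outcome = "age", sheet = s,
                                      quiet = TRUE)
  beta <- betaValues(me)
  sel_fixed <- if (fixed_selection)
    selectClockCpgs(ewas_fn(me, sheet), me, k = k) else NULL
  preds <- numeric(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    me_tr <- me[, tr]
    sh_tr <- sheet[tr, , drop = FALSE]
    sel <- if (fixed_selection) sel_fixed else
      tryCatch(selectClockCpgs(ewas_fn(me_tr, sh_tr), me_tr, k = k),
               error = function(e)
                 stop("fold ", i, ": ", conditionMessage(e)))
    model <- tryCatch(
      trainAgeClock(beta[sel, tr, drop = FALSE], ages[tr], alpha = alpha,
                    nlambda = nlambda,
                    lambda_min_ratio = lambda_min_ratio),
      error = function(e) stop("fold ", i, ": ", conditionMessage(e)))
    preds[i] <- predictAge(model, beta[sel, i, drop = FALSE],
                           impute = TRUE)
  }
  abs_err <- abs(preds - ages)
  final_sel <- if (fixed_selection) sel_fixed else
    selectClockCpgs(ewas_fn(me, sheet), me, k = k)
  final <- trainAgeClock(beta[final_sel, , drop = FALSE], ages,
                         alpha = alpha, nlambda = nlambda,
                         lambda_min_ratio = lambda_min_ratio)
  list(evaluation = data.frame(sample = colnames(me), age = ages,
                               predicted = preds, abs_error = abs_err,
                               stringsAsFactors = FALSE),
       mae = mean(abs_err), n = n, model = final,
       fixed_selection = fixed_selection)
}

#' Serialize / restore a clock model as plain text
#'
#' A portable tab-delimited table (cpg id, chromosome, 0-based position,
#' coefficient, training mean) preceded by a `#`-prefixed header block
#' (intercept, alpha, lambda, training n).
#'
#' @param model an [AgeClockModel-class]
#' @param path file path
#' @export
writeClockModel <- function(model, path) {
  hdr <- c(paste0("# intercept\t", format(model@intercept, digits = 17)),
           paste0("# alpha\t", model@alpha),
           paste0("# lambda\t", format(model@lambda, digits = 17)),
           paste0("# training_n\t", model@training_n))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  sp <- strsplit(model@cpg_ids, ":", fixed = TRUE)
  df <- data.frame(cpg_id = model@cpg_ids,
                   chrom = vapply(sp, `[`, "", 1L),
                   pos = vapply(sp, `[`, "", 2L),
                   coefficient = format(model@coefficients, digits = 17),
                   training_mean = format(
                     model@feature_selection$training_means[model@cpg_ids],
                     digits = 17))
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' @rdname writeClockModel
#' @export
readClockModel <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  getv <- function(key) {
    ln <- hdr[grepl(paste0("^# ", key, "\t"), hdr)]
    strsplit(ln, "\t", fixed = TRUE)[[1]][2]
  }
  df <- read.table(text = lines[!startsWith(lines, "#")], sep = "\t",
                   header = TRUE, stringsAsFactors = FALSE)
  new("AgeClockModel",
      cpg_ids = df$cpg_id, intercept = as.numeric(getv("intercept")),
      coefficients = as.numeric(df$coefficient),
      alpha = as.numeric(getv("alpha")),
      lambda = as.numeric(getv("lambda")), lambda_grid = numeric(0),
      training_n = as.integer(getv("training_n")),
      feature_selection = list(
        training_means = setNames(as.numeric(df$training_mean),
                                  df$cpg_id)))
}
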