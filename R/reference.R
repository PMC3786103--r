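#' Reference GA-MLR model tables for dihydropyridine calcium channel blockers
#'
#' A literature GA-MLR QSAR model of 1,4-dihydropyridine L-type calcium
#' channel blockers (36 compounds, five Dragon descriptors: BELm6, E1m,
#' E2v, HATS8m, R2e+) is embedded here as a fixture: its reported
#' coefficient estimates with standard errors, fit/validation statistics,
#' descriptor correlation matrix, variance inflation factors, mean
#' effects, and Y-randomization table. The underlying compound-level
#' descriptor matrix was never published, so these tables support
#' report-formatting and consistency checks, not refitting.
#'
#' @return object of class `dhp_reference`: list with
#'   \describe{
#'     \item{descriptors}{the five descriptor names}
#'     \item{correlations}{5 x 5 symmetric descriptor correlation matrix
#'       (mirrored from the reported lower triangle)}
#'     \item{vif}{the five reported variance inflation factors}
#'     \item{mean_effects}{the five reported mean effects (intercept 0)}
#'     \item{coefficients}{named vector: intercept and five slopes}
#'     \item{std_errors}{their reported standard deviations}
#'     \item{stats}{named list of the reported statistics block
#'       (r2_train, r2_test, r2_adj, f_train, q2_loo, q2_lgo, q2_boot,
#'       rmse_train, rmse_test, n_train, n_test)}
#'     \item{y_randomization}{data.frame (no, q2, r2) of the ten reported
#'       response-permutation refits}
#'   }
#' @export
#' @examples
#' ref <- dhp_reference()
#' ref$correlations["E1m", "BELm6"]
#' sum(ref$mean_effects)  # 1 by construction of the mean effect
dhp_reference <- function() {
  descriptors <- c("BELm6", "E1m", "E2v", "HATS8m", "R2e+")
  R <- diag(5)
  dimnames(R) <- list(descriptors, descriptors)
  R["E1m", "BELm6"] <- -0.32678
  R["E2v", "BELm6"] <- 0.023974
  R["E2v", "E1m"] <- -0.20311
  R["HATS8m", "BELm6"] <- -0.59
  R["HATS8m", "E1m"] <- 0.688288
  R["HATS8m", "E2v"] <- -0.16102
  R["R2e+", "BELm6"] <- -0.19761
  R["R2e+", "E1m"] <- 0.223311
  R["R2e+", "E2v"] <- -0.35277
  R["R2e+", "HATS8m"] <- 0.508854
  R[upper.tri(R)] <- t(R)[upper.tri(R)]
  structure(list(
    descriptors = descriptors,
    correlations = R,
    vif = stats::setNames(
      c(1.47149272, 1.889935834, 1.062263659, 3.166979174, 1.500297586),
      descriptors),
    mean_effects = stats::setNames(
      c(0.746010645, -0.138362847, -0.259229493, 0.22801657, 0.423565125),
      descriptors),
    coefficients = stats::setNames(
      c(-2.1301, 1.457617, -1.08595, -2.25419, 3.7547, 19.65472),
      c("(Intercept)", descriptors)),
    std_errors = stats::setNames(
      c(0.951352, 0.585674, 0.233582, 0.369137, 1.007998, 4.570518),
      c("(Intercept)", descriptors)),
    stats = list(r2_train = 0.86, r2_test = 0.435, r2_adj = 0.830,
                 f_train = 28.26, q2_loo = 0.802, q2_lgo = 0.792,
                 q2_boot = 0.796, rmse_train = 0.0715, rmse_test = 0.2826,
                 n_train = 29L, n_test = 7L),
    y_randomization = data.frame(
      no = 1:10,
      q2 = c(0.019534, 0.000557, 1.79e-05, 0.047437, 0.000167,
             0.316241, 0.026796, 0.141785, 0.19683, 0.000406),
      r2 = c(0.287701, 0.242321, 0.228966, 0.119975, 0.19419,
             0.060208, 0.127187, 0.09585, 0.063782, 0.215877))),
    class = "dhp_reference")
}

#' Write the reference tables as delimited text files
#'
#' Emits `dhp_correlations.tsv` (correlation matrix), `dhp_model.tsv`
#' (descriptor, coefficient, std_error, MF, VIF), and
#' `dhp_y_randomization.tsv` into a directory.
#'
#' @param dir output directory (created if needed).
#' @return character vector of the written paths, invisibly.
#' @export
write_reference_tables <- function(dir) {
  ref <- dhp_reference()
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "dhp_correlations.tsv")
  utils::write.table(data.frame(descriptor = rownames(ref$correlations),
                                ref$correlations, check.names = FALSE),
                     p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- file.path(dir, "dhp_model.tsv")
  utils::write.table(data.frame(
    descriptor = c("(Intercept)", ref$descriptors),
    coefficient = ref$coefficients,
    std_error = ref$std_errors,
    mean_effect = c(0, ref$mean_effects),
    vif = c(NA, ref$vif), check.names = FALSE),
    p2, sep = "\t", quote = FALSE, row.names = FALSE)
  p3 <- file.path(dir, "dhp_y_randomization.tsv")
  utils::write.table(ref$y_randomization, p3, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(p1, p2, p3))
}
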