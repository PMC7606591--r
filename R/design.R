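#' Build the vertex-wise GLM design matrix
#'
#' Columns follow the morphometry model
#' `Y = b0 + b1*site + b2*group + b3*age + b4*age^2 + b5*(age x group)
#'  + b6*(age^2 x group) + b7*sex + b8*iq + b9*related + b10*total_sa`,
#' with the age polynomial order selectable for nested model comparison.
#' Categorical factors are 0/1 indicators (reference levels: site A,
#' control, female, unrelated). Continuous covariates (age, IQ, total SA)
#' are mean-centered across the combined sample; age powers are computed
#' from centered age and then re-centered to limit collinearity, and
#' interactions are formed from the centered terms.
#'
#' @param cohort a `cohort_table`.
#' @param age_order 1 (linear), 2 (quadratic) or 3 (cubic).
#' @param with_interactions include age-power-by-group interactions.
#' @param include_iq include the IQ covariate (on by default; toggleable
#'   because covariate sets vary between reports of this model).
#' @param include_total_sa include total surface area as covariate.
#' @param group_column column coded 1 for the second level; default
#'   `"group"` with `case = 1`.
#' @return a `design_matrix`: list with `X` (n x p named matrix),
#'   `centering` (named means subtracted), `age_order`.
#' @examples
#' X <- build_design(generate_cohort(seed = 1), age_order = 2)
#' colnames(X$X)  # 11 columns, intercept through total_sa
#' @export
build_design <- function(cohort, age_order = 2, with_interactions = TRUE,
                         include_iq = TRUE, include_total_sa = TRUE,
                         group_column = "group") {
  stopifnot(age_order %in% 1:3)
  needed <- c(group_column, "age", "sex", "site", "related")
  if (include_iq) needed <- c(needed, "iq")
  if (include_total_sa) needed <- c(needed, "total_sa")
  miss <- setdiff(needed, names(cohort))
  if (length(miss)) stop("cohort missing covariates: ",
                         paste(miss, collapse = ", "))
  if (anyNA(cohort[needed])) stop("cohort covariates contain NA")

  n <- nrow(cohort)
  gvals <- cohort[[group_column]]
  glev <- sort(unique(gvals))
  if (length(glev) != 2L) stop("group column must have exactly 2 levels")
  # reference = control if present, else first sorted level
  ref <- if ("control" %in% glev) "control" else glev[1L]
  group <- as.numeric(gvals != ref)

  centering <- c(age = mean(cohort$age))
  cage <- cohort$age - centering[["age"]]
  powers <- list(cage)
  if (age_order >= 2) powers[[2]] <- cage^2
  if (age_order >= 3) powers[[3]] <- cage^3
  pw_names <- c("age", "age2", "age3")[seq_len(age_order)]
  for (k in seq_along(powers)) {
    centering[pw_names[k]] <- mean(powers[[k]])
    powers[[k]] <- powers[[k]] - mean(powers[[k]])
  }

  cols <- list(intercept = rep(1, n),
               site = as.numeric(cohort$site == "B"),
               group = group)
  for (k in seq_along(powers)) cols[[pw_names[k]]] <- powers[[k]]
  if (with_interactions) {
    for (k in seq_along(powers)) {
      cols[[paste0(pw_names[k], "_x_group")]] <- powers[[k]] * group
    }
  }
  cols$sex <- as.numeric(cohort$sex == "M")
  if (include_iq) {
    centering["iq"] <- mean(cohort$iq)
    cols$iq <- cohort$iq - centering[["iq"]]
  }
  cols$related <- as.numeric(cohort$related == "yes")
  if (include_total_sa) {
    centering["total_sa"] <- mean(cohort$total_sa)
    cols$total_sa <- cohort$total_sa - centering[["total_sa"]]
  }

  X <- do.call(cbind, cols)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  structure(list(X = X, centering = centering, age_order = age_order,
                 with_interactions = with_interactions),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design_matrix: %d subjects x %d columns (age order %d)\n",
              nrow(x$X), ncol(x$X), x$age_order))
  cat("  columns:", paste(colnames(x$X), collapse = ", "), "\n")
  invisible(x)
}
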