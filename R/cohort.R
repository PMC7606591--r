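## Synthetic two-group cohort generation.
##
## Defaults emulate the demographic and global-brain marginals of a
## two-site 22q11.2 deletion cohort study: 62 cases vs 57 controls aged
## 6-31, case IQ ~ 82 (sd 13) vs control 114 (sd 16), reduced total
## surface area in cases (0.20 vs 0.23 m^2) with matched mean cortical
## thickness (2.72 vs 2.73 mm) and total grey volume. The total-SA spread
## (sd 0.0275 m^2 per group) is set so the standardized group difference
## is about d = 1.09, consistent with a two-sample t near -5.95 at
## n = 62 + 57.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
  }
  x
}

balanced_levels <- function(n, levels) {
  sample(rep(levels, length.out = n))
}

#' Generate a synthetic two-group cohort table
#'
#' Draws per-subject demographics and global brain measures for a
#' case/control developmental cohort. Total cortical volume is the product
#' of mean thickness and total surface area (1 mm x 1 m^2 = 1 L) with
#' small multiplicative noise, so the global measures carry the same
#' thickness-area-volume structure as the vertex-wise generator.
#'
#' @param n_case,n_control group sizes (> 0).
#' @param age_range length-2 numeric, years.
#' @param seed integer seed; fixed seed gives an identical table.
#' @param iq_case,iq_control mean and sd of full-scale IQ per group.
#' @param total_sa_case,total_sa_control mean and sd of total surface
#'   area, m^2.
#' @param mean_ct_case,mean_ct_control mean and sd of whole-brain mean
#'   cortical thickness, mm.
#' @param prodromal_rate probability a case shows prodromal psychosis
#'   symptoms (controls are `"n/a"`).
#' @return a `data.frame` (class `cohort_table`) with columns
#'   `subject_id`, `group`, `age`, `sex`, `site`, `iq`, `related`,
#'   `total_sa`, `mean_ct`, `total_cv`, `psychosis_prodromal`.
#' @examples
#' coh <- generate_cohort(seed = 1)
#' table(coh$group)
#' @export
generate_cohort <- function(n_case = 62, n_control = 57,
                            age_range = c(6, 31), seed = 1,
                            iq_case = c(82, 13), iq_control = c(114, 16),
                            total_sa_case = c(0.20, 0.0275),
                            total_sa_control = c(0.23, 0.0275),
                            mean_ct_case = c(2.72, 0.14),
                            mean_ct_control = c(2.73, 0.12),
                            prodromal_rate = 9 / 62) {
  if (n_case < 1 || n_control < 1) stop("both groups must be non-empty")
  stopifnot(length(age_range) == 2, age_range[1] < age_range[2])
  with_seed(seed, {
    n <- n_case + n_control
    group <- rep(c("case", "control"), c(n_case, n_control))
    age <- c(
      rnorm_trunc(n_case, 16, 7, age_range[1], age_range[2]),
      rnorm_trunc(n_control, 15, 6, age_range[1], age_range[2])
    )
    iq <- c(
      rnorm_trunc(n_case, iq_case[1], iq_case[2], lower = 60),
      rnorm_trunc(n_control, iq_control[1], iq_control[2], lower = 60)
    )
    total_sa <- c(
      rnorm_trunc(n_case, total_sa_case[1], total_sa_case[2], lower = 0.05),
      rnorm_trunc(n_control, total_sa_control[1], total_sa_control[2],
                  lower = 0.05)
    )
    mean_ct <- c(
      rnorm_trunc(n_case, mean_ct_case[1], mean_ct_case[2], lower = 1),
      rnorm_trunc(n_control, mean_ct_control[1], mean_ct_control[2],
                  lower = 1)
    )
    total_cv <- mean_ct * total_sa * exp(stats::rnorm(n, 0, 0.05))
    # exact-count assignment so the indicator marginals are hit exactly
    # and never degenerate to a constant column in small cohorts
    draw_exact <- function(n_, rate, yes = "yes", no = "no") {
      k <- max(1L, min(n_ - 1L, round(rate * n_)))
      sample(rep(c(yes, no), c(k, n_ - k)))
    }
    related <- c(draw_exact(n_case, 0.06), draw_exact(n_control, 0.23))
    prodromal <- c(draw_exact(n_case, prodromal_rate),
                   rep("n/a", n_control))
    out <- data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      group = group,
      age = age,
      sex = c(balanced_levels(n_case, c("M", "F")),
              balanced_levels(n_control, c("M", "F"))),
      site = c(balanced_levels(n_case, c("A", "B")),
               balanced_levels(n_control, c("A", "B"))),
      iq = iq,
      related = related,
      total_sa = total_sa,
      mean_ct = mean_ct,
      total_cv = total_cv,
      psychosis_prodromal = prodromal,
      stringsAsFactors = FALSE
    )
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}

#' Read / write a cohort covariate table
#'
#' Plain CSV with the [generate_cohort()] column set.
#'
#' @param path CSV file path.
#' @return `read_cohort` returns a `cohort_table`.
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "group", "age", "sex", "site", "iq", "related",
              "total_sa")
  missing <- setdiff(needed, names(out))
  if (length(missing)) {
    stop("cohort table missing columns: ", paste(missing, collapse = ", "))
  }
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' @rdname read_cohort
#' @param cohort a `cohort_table`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
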