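# Marginal summaries the generator emulates: clipped normals with the
# printed mean/sd/range of the source ED population, plus categorical
# mixes.  Values at the range boundary are produced by clipping, so every
# generated value lies inside the printed range.
.ed_numeric_marginals <- function() {
  list(
    age              = c(mean = 42.46,  sd = 24.83,  lo = 0,     hi = 107),
    bmi              = c(mean = 28.56,  sd = 7.804,  lo = 7.38,  hi = 50.68),
    systolic_bp      = c(mean = 121.01, sd = 15.016, lo = 69,    hi = 168),
    diastolic_bp     = c(mean = 72.99,  sd = 10.802, lo = 35,    hi = 107),
    pulse_rate       = c(mean = 82.71,  sd = 16.051, lo = 34,    hi = 130),
    temperature      = c(mean = 97.87,  sd = 0.8,    lo = 94.4,  hi = 100.6),
    o2_saturation    = c(mean = 97.54,  sd = 1.968,  lo = 92,    hi = 100),
    respiratory_rate = c(mean = 16.92,  sd = 2.122,  lo = 12,    hi = 23),
    waiting_time     = c(mean = 9.31,   sd = 11.579, lo = 0,     hi = 51)
  )
}

.ed_categorical_marginals <- function() {
  list(
    location_id = c("10001" = 0.2761, "10025" = 0.1622,
                    "10026" = 0.2032, "15001" = 0.3586),
    sex         = c(Male = 0.5352, Female = 0.4648),
    ethnicity   = c("Not Hispanic or Latino" = 0.0478,
                    "Hispanic or Latino"     = 0.9522),
    smoking_status = c("Current Smoker" = 0.2363, "Former Smoker" = 0.0107,
                       "Never Smoker"   = 0.0529, "Unknown"       = 0.70)
  )
}

# mean and sd of clip(N(mu, sd), lo, hi) in closed form; the oracle the
# generator's marginal tests compare against
.clipped_normal_moments <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd; b <- (hi - mean) / sd
  Fa <- stats::pnorm(a); Fb <- stats::pnorm(b)
  fa <- stats::dnorm(a); fb <- stats::dnorm(b)
  m1 <- lo * Fa + hi * (1 - Fb) + mean * (Fb - Fa) + sd * (fa - fb)
  # E[X^2] split over the three pieces of the clipped variable
  mid2 <- (mean^2 + sd^2) * (Fb - Fa) +
    sd^2 * (a * fa - b * fb) + 2 * mean * sd * (fa - fb)
  m2 <- lo^2 * Fa + hi^2 * (1 - Fb) + mid2
  c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generator settings for synthetic ED visits
#'
#' @param n Number of visits.
#' @param prevalence Target fraction of LAMA (positive) visits, in (0,1);
#'   default 0.0066, the prevalence of the emulated ED population.
#' @param effects Named numeric vector of planted log-odds coefficients,
#'   per standard deviation of the named (encoded) feature.  Names must
#'   match encoded feature names (e.g. `esi`, `waiting_time`,
#'   `loc_15001`).  Empty means a label independent of all features.
#' @param vitals_rho Correlation between pulse rate and respiratory rate
#'   (latent normal scale); the printed source marginals carry no joint
#'   structure, but cross-feature correlation is what makes neighbour-based
#'   imputation testable.
#' @param zip_pool Number of distinct zip codes drawn from the printed
#'   range (10016, 99750).
#' @param seed Integer seed.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n, prevalence = 0.0066, effects = numeric(0),
                             vitals_rho = 0.4, zip_pool = 20L, seed = 1L) {
  stopifnot(n >= 1, prevalence > 0, prevalence < 1,
            abs(vitals_rho) < 1, zip_pool >= 2)
  if (length(effects) && is.null(names(effects)))
    stop("effects must be a named vector", call. = FALSE)
  structure(list(n = as.integer(n), prevalence = prevalence,
                 effects = effects, vitals_rho = vitals_rho,
                 zip_pool = as.integer(zip_pool), seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a synthetic table of ED visits with a planted outcome signal
#'
#' Emulates the schema and marginals of the source ED population:
#' four location IDs, demographics (age, sex, zip code, ethnicity, BMI,
#' 4-level smoking status), vital signs (systolic/diastolic blood
#' pressure, pulse, temperature, O2 saturation, respiratory rate), ESI
#' acuity in \{2..5\}, arrival day/month/hour, and waiting time in
#' minutes.  Numeric columns are clipped normals matching the printed
#' mean, sd and range; pulse and respiratory rate share a configurable
#' latent correlation; ESI is a discretized latent normal.  The binary
#' disposition label (`ed_disposition`: `"LAMA"` / `"SAT"`) follows a
#' logistic model on the standardized encoded features named in
#' `config$effects`, with the intercept calibrated numerically so the
#' expected prevalence equals `config$prevalence`.
#'
#' @param config A [generator_config()].
#' @return List of class `ed_visits`: `visits` (raw data.frame, one row
#'   per visit) and `truth` (planted mechanism: standardized
#'   coefficients, intercept, feature scaling, a Monte-Carlo estimate of
#'   the Bayes-optimal AUC, and the seed).
#' @examples
#' g <- generate_visits(generator_config(500, prevalence = 0.05, seed = 2))
#' table(g$visits$ed_disposition)
#' @export
generate_visits <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n
  num <- .ed_numeric_marginals()
  cat_ <- .ed_categorical_marginals()

  draw_clip <- function(p) .clip(stats::rnorm(n, p[["mean"]], p[["sd"]]),
                                 p[["lo"]], p[["hi"]])
  draw_cat <- function(p) sample(names(p), n, replace = TRUE, prob = p)

  # correlated latent pair for pulse / respiratory rate
  z1 <- stats::rnorm(n)
  z2 <- config$vitals_rho * z1 +
    sqrt(1 - config$vitals_rho^2) * stats::rnorm(n)
  pu <- num$pulse_rate; rr <- num$respiratory_rate

  # ESI: discretized latent normal on {2..5}
  esi <- .clip(round(stats::rnorm(n, 3.23, 0.633)), 2, 5)

  visits <- data.frame(
    location_id      = draw_cat(cat_$location_id),
    age              = draw_clip(num$age),
    sex              = draw_cat(cat_$sex),
    zip_code         = sample(round(seq(10016, 99750,
                                        length.out = config$zip_pool)),
                              n, replace = TRUE),
    ethnicity        = draw_cat(cat_$ethnicity),
    bmi              = draw_clip(num$bmi),
    smoking_status   = draw_cat(cat_$smoking_status),
    systolic_bp      = draw_clip(num$systolic_bp),
    diastolic_bp     = draw_clip(num$diastolic_bp),
    pulse_rate       = .clip(pu[["mean"]] + pu[["sd"]] * z1,
                             pu[["lo"]], pu[["hi"]]),
    temperature      = draw_clip(num$temperature),
    o2_saturation    = draw_clip(num$o2_saturation),
    respiratory_rate = .clip(rr[["mean"]] + rr[["sd"]] * z2,
                             rr[["lo"]], rr[["hi"]]),
    esi              = esi,
    day_of_month     = sample(1:31, n, replace = TRUE),
    month            = sample(1:12, n, replace = TRUE),
    hour             = sample(0:23, n, replace = TRUE),
    waiting_time     = draw_clip(num$waiting_time),
    stringsAsFactors = FALSE
  )

  # planted mechanism on the standardized encoded features
  enc <- encode_visits(cbind(visits, ed_disposition = "SAT"))
  X <- as.matrix(enc[, setdiff(names(enc), "lama"), drop = FALSE])
  eff <- config$effects
  unknown <- setdiff(names(eff), colnames(X))
  if (length(unknown))
    stop("effects name unknown encoded features: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  lp <- numeric(n)
  scaling <- NULL
  if (length(eff)) {
    mu <- colMeans(X[, names(eff), drop = FALSE])
    sg <- apply(X[, names(eff), drop = FALSE], 2, stats::sd)
    sg[sg == 0] <- 1
    Z <- sweep(sweep(X[, names(eff), drop = FALSE], 2, mu), 2, sg, "/")
    lp <- drop(Z %*% eff)
    scaling <- list(center = mu, scale = sg)
  }

  # calibrate the intercept so E[p] hits the target prevalence
  f <- function(b0) mean(stats::plogis(b0 + lp)) - config$prevalence
  intercept <- stats::uniroot(f, c(-40, 40), tol = 1e-10)$root
  p <- stats::plogis(intercept + lp)
  y <- stats::rbinom(n, 1L, p)
  visits$ed_disposition <- ifelse(y == 1L, "LAMA", "SAT")

  bayes_auc <- if (length(eff) && length(unique(y)) == 2L)
    auc_rank(lp, y) else 0.5

  structure(list(
    visits = visits,
    truth = list(effects = eff, intercept = intercept, scaling = scaling,
                 prevalence = config$prevalence, bayes_auc = bayes_auc,
                 seed = config$seed)), class = "ed_visits")
}

#' Inject missing values into a visit table
#'
#' Sets cells of the given columns to `NA` at the configured rates,
#' optionally with class-conditional rates to emulate outcome-dependent
#' missingness.
#'
#' @param visits Raw visit data.frame (with `ed_disposition`).
#' @param rates Either a single rate for all listed columns or a named
#'   vector of per-column rates in \[0, 1).
#' @param columns Columns to degrade; default: all except the label.
#' @param class_rates Optional named list mapping a column to
#'   `c(LAMA = r1, SAT = r0)` per-class rates (overrides `rates` for that
#'   column).
#' @param seed Integer seed.
#' @return The data.frame with `NA`s injected.
#' @export
degrade <- function(visits, rates, columns = NULL, class_rates = NULL,
                    seed = 1L) {
  set.seed(seed)
  if (is.null(columns))
    columns <- setdiff(names(visits), "ed_disposition")
  if (length(rates) == 1L && is.null(names(rates)))
    rates <- stats::setNames(rep(rates, length(columns)), columns)
  stopifnot(all(rates >= 0), all(rates < 1))
  for (cl in columns) {
    if (!is.null(class_rates) && cl %in% names(class_rates)) {
      rr <- class_rates[[cl]]
      for (lab in names(rr)) {
        idx <- which(visits$ed_disposition == lab)
        hit <- idx[stats::runif(length(idx)) < rr[[lab]]]
        visits[hit, cl] <- NA
      }
    } else if (cl %in% names(rates) && rates[[cl]] > 0) {
      hit <- which(stats::runif(nrow(visits)) < rates[[cl]])
      visits[hit, cl] <- NA
    }
  }
  visits
}
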