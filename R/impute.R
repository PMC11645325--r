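# Canonical raw-schema metadata: categorical levels (first level = the
# dropped one-hot reference) and the numeric columns.
.raw_categoricals <- function() {
  list(
    location_id    = c("10001", "10025", "10026", "15001"),
    sex            = c("Female", "Male"),
    ethnicity      = c("Hispanic or Latino", "Not Hispanic or Latino"),
    smoking_status = c("Unknown", "Current Smoker", "Former Smoker",
                       "Never Smoker")
  )
}

.dummy_name <- function(col, level) {
  lv <- tolower(gsub("[^A-Za-z0-9]+", "_", level))
  switch(col,
         location_id    = paste0("loc_", level),
         sex            = paste0("sex_", lv),
         ethnicity      = paste0("ethnicity_",
                                 if (grepl("^Not", level)) "not_hispanic"
                                 else "hispanic"),
         smoking_status = paste0("smoker_", sub("_smoker$", "", lv)),
         paste0(col, "_", lv))
}

#' Encode a raw visit table for modelling
#'
#' Applies the preprocessing rules of the LAMA framework: every
#' c-category feature becomes c−1 binary indicators (reference levels:
#' location `10001`, `Female`, `Hispanic or Latino`, smoking `Unknown`);
#' repeated vital-sign readings (columns like `pulse_rate_1`,
#' `pulse_rate_2`) are averaged into one column; a timestamp column
#' `arrival_time`, if present, is reduced to `month` and `hour` and
#' dropped; waiting time passes through in minutes; the disposition label
#' is coded `lama` = 1 (LAMA) / 0 (SAT).
#'
#' @param raw Raw data.frame in the generator's schema (see
#'   [generate_visits()]); `ed_disposition` must hold `"LAMA"`/`"SAT"`.
#' @return A `visit_table`: an all-numeric data.frame whose `"schema"`
#'   attribute records each column's kind (`"numeric"` or `"binary"`) and
#'   the label column name.
#' @export
encode_visits <- function(raw) {
  stopifnot(is.data.frame(raw), "ed_disposition" %in% names(raw))
  raw <- as.data.frame(raw, stringsAsFactors = FALSE)

  # timestamp reduction
  if ("arrival_time" %in% names(raw)) {
    tt <- as.POSIXlt(raw$arrival_time)
    if (!"month" %in% names(raw)) raw$month <- tt$mon + 1L
    if (!"hour" %in% names(raw))  raw$hour <- tt$hour
    raw$arrival_time <- NULL
  }

  # average repeated vital-sign readings: foo_1, foo_2, ... -> foo
  rep_cols <- grep("^(systolic_bp|diastolic_bp|pulse_rate|temperature|o2_saturation|respiratory_rate)_[0-9]+$",
                   names(raw), value = TRUE)
  if (length(rep_cols)) {
    base <- unique(sub("_[0-9]+$", "", rep_cols))
    for (b in base) {
      grp <- grep(paste0("^", b, "_[0-9]+$"), names(raw), value = TRUE)
      raw[[b]] <- rowMeans(raw[grp], na.rm = TRUE)
      raw[[b]][is.nan(raw[[b]])] <- NA
      raw[grp] <- NULL
    }
  }

  bad <- !raw$ed_disposition %in% c("LAMA", "SAT") & !is.na(raw$ed_disposition)
  if (any(bad)) stop("unknown disposition label", call. = FALSE)
  lama <- as.integer(raw$ed_disposition == "LAMA")

  cats <- .raw_categoricals()
  out <- list()
  kinds <- character(0)
  for (col in setdiff(names(raw), "ed_disposition")) {
    v <- raw[[col]]
    if (col %in% names(cats)) {
      levels_ <- cats[[col]]
      unknown <- setdiff(unique(v[!is.na(v)]), levels_)
      if (length(unknown))
        stop("unknown categories in '", col, "': ",
             paste(unknown, collapse = ", "), call. = FALSE)
      for (lev in levels_[-1L]) {        # first level is the reference
        nm <- .dummy_name(col, lev)
        out[[nm]] <- ifelse(is.na(v), NA_integer_, as.integer(v == lev))
        kinds[nm] <- "binary"
      }
    } else if (is.numeric(v)) {
      out[[col]] <- v
      kinds[col] <- if (all(v %in% c(0, 1, NA))) "binary" else "numeric"
    } else {
      stop("column '", col, "' is neither numeric nor a known categorical",
           call. = FALSE)
    }
  }
  out$lama <- lama
  kinds["lama"] <- "binary"
  vt <- as.data.frame(out, check.names = FALSE)
  attr(vt, "schema") <- list(kinds = kinds, label = "lama")
  class(vt) <- c("visit_table", "data.frame")
  vt
}

#' @export
print.visit_table <- function(x, ...) {
  sc <- attr(x, "schema")
  cat("visit_table:", nrow(x), "visits,", ncol(x) - 1L,
      "features, label:", sc$label, "\n")
  print(utils::head(as.data.frame(x), 4))
  invisible(x)
}

# nan-aware squared Euclidean distances between all rows of a matrix that
# may contain NAs, on the standardized scale, rescaled by p/shared as in
# the standard KNN imputer.  Returns an n x n matrix (diag = Inf).
.nan_dist2 <- function(Z) {
  M <- !is.na(Z)
  X0 <- Z; X0[!M] <- 0
  A <- X0^2
  Mn <- M * 1
  S <- Mn %*% t(Mn)                      # shared observed dims
  D2 <- A %*% t(Mn) + Mn %*% t(A) - 2 * X0 %*% t(X0)
  D2[D2 < 0] <- 0                        # numeric noise
  p <- ncol(Z)
  D2 <- D2 * p / pmax(S, 1)
  D2[S == 0] <- Inf                      # no shared dims: incomparable
  diag(D2) <- Inf
  D2
}

#' K-nearest-neighbour imputation
#'
#' Replaces each missing cell by the average of the `k` nearest rows'
#' values in that column.  Distance is nan-aware Euclidean over the
#' standardized numeric columns (binary 0/1 columns enter unscaled;
#' dimensions missing in either row are skipped and the distance rescaled
#' accordingly).  Binary and categorical cells are imputed by
#' neighbour vote (the neighbour mean thresholded at 0.5 for 0/1
#' columns, the majority level for character/factor columns).  Observed
#' cells are never modified, so a complete table passes through
#' unchanged.
#'
#' @param data A data.frame: raw (mixed numeric/character) or an encoded
#'   `visit_table`.
#' @param k Number of donor neighbours, >= 1.
#' @param exclude Columns excluded from both the distance and the
#'   imputation (default: the label column `ed_disposition` / the encoded
#'   label, if present).
#' @return The completed data.frame (same class and attributes).
#' @export
knn_impute <- function(data, k = 5L, exclude = NULL) {
  stopifnot(is.data.frame(data), k >= 1)
  k <- as.integer(k)
  if (is.null(exclude))
    exclude <- intersect(c("ed_disposition", "lama"), names(data))
  cols <- setdiff(names(data), exclude)
  if (!anyNA(data[cols])) return(data)

  num_cols <- cols[vapply(data[cols], is.numeric, logical(1))]
  chr_cols <- setdiff(cols, num_cols)
  is_bin <- vapply(num_cols, function(cl)
    all(data[[cl]] %in% c(0, 1, NA)), logical(1))

  # standardized numeric block for the distance
  Z <- as.matrix(data[num_cols])
  storage.mode(Z) <- "double"
  for (j in seq_along(num_cols)) {
    if (is_bin[j]) next
    v <- Z[, j]
    mu <- mean(v, na.rm = TRUE)
    sg <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(sg) || sg == 0) sg <- 1
    Z[, j] <- (v - mu) / sg
  }
  D2 <- .nan_dist2(Z)

  out <- data
  for (cl in cols) {
    miss <- which(is.na(data[[cl]]))
    if (!length(miss)) next
    donors <- which(!is.na(data[[cl]]))
    if (length(donors) < k)
      stop("column '", cl, "' has fewer than k observed rows", call. = FALSE)
    for (i in miss) {
      d <- D2[i, donors]
      nb <- donors[order(d, donors)[seq_len(k)]]   # deterministic ties
      vals <- data[[cl]][nb]
      out[i, cl] <- if (cl %in% chr_cols) {
        tab <- sort(table(vals), decreasing = TRUE)
        names(tab)[1L]
      } else if (cl %in% num_cols && is_bin[match(cl, num_cols)]) {
        as.numeric(mean(vals) >= 0.5)
      } else {
        mean(vals)
      }
    }
  }
  out
}

#' Withhold observed cells at random for imputation validation
#'
#' Masks a uniformly random subset of the observed, non-label cells
#' (each cell independently with probability `fraction`) and records the
#' masked positions so the imputation can be scored against the truth.
#'
#' @param data A complete data.frame.
#' @param fraction Fraction of cells to mask, in (0, 1).
#' @param exclude Columns never masked (default: label columns).
#' @param seed Integer seed.
#' @return List: `masked` (the data with `NA`s), `mask` (data.frame
#'   `row`, `column`, `original`).
#' @export
inject_missingness <- function(data, fraction = 0.1, exclude = NULL,
                               seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  set.seed(seed)
  if (is.null(exclude))
    exclude <- intersect(c("ed_disposition", "lama"), names(data))
  cols <- setdiff(names(data), exclude)
  masked <- data
  rows <- integer(0); colv <- character(0); orig <- list()
  for (cl in cols) {
    obs <- which(!is.na(data[[cl]]))
    hit <- obs[stats::runif(length(obs)) < fraction]
    if (!length(hit)) next
    rows <- c(rows, hit)
    colv <- c(colv, rep(cl, length(hit)))
    orig <- c(orig, as.list(data[[cl]][hit]))
    masked[hit, cl] <- NA
  }
  list(masked = masked,
       mask = data.frame(row = rows, column = colv,
                         original = I(unlist(orig)),
                         stringsAsFactors = FALSE))
}

#' Validate KNN imputation by artificial missingness (MAPE protocol)
#'
#' Implements the imputation validation protocol: starting from a
#' complete table, withhold `fraction` of the cells at random, re-impute
#' them with [knn_impute()], and score each numeric feature by the mean
#' absolute percentage error over its masked cells only,
#' `100 * mean(|original - imputed| / |original|)`.  Masked cells whose
#' original value is zero are excluded from the MAPE and counted.
#' Binary/categorical features are scored by mismatch rate instead.
#' A vector `k` produces one report block per K, so K can be chosen
#' empirically.
#'
#' @param data A complete data.frame (raw or encoded).
#' @param fraction Fraction of cells to withhold (default 0.1).
#' @param k Donor count, scalar or vector.
#' @param seed Integer seed (the same mask is reused across the K grid).
#' @return An `imputation_report`: data.frame with columns `feature`,
#'   `k`, `metric` (`"mape_pct"` or `"mismatch_rate"`), `value`,
#'   `n_masked`, `n_zero_excluded`.
#' @export
validate_imputation <- function(data, fraction = 0.1, k = 5L, seed = 1L) {
  if (anyNA(data)) stop("validation requires a complete table", call. = FALSE)
  inj <- inject_missingness(data, fraction, seed = seed)
  res <- list()
  for (kk in k) {
    completed <- knn_impute(inj$masked, k = kk)
    for (cl in unique(inj$mask$column)) {
      sel <- inj$mask$column == cl
      ridx <- inj$mask$row[sel]
      original <- data[[cl]][ridx]
      imputed <- completed[[cl]][ridx]
      if (is.numeric(original) && !all(original %in% c(0, 1))) {
        zero <- original == 0
        val <- if (all(zero)) NA_real_ else
          100 * mean(abs(original[!zero] - imputed[!zero]) /
                       abs(original[!zero]))
        res[[length(res) + 1L]] <- data.frame(
          feature = cl, k = kk, metric = "mape_pct", value = val,
          n_masked = length(ridx), n_zero_excluded = sum(zero))
      } else {
        res[[length(res) + 1L]] <- data.frame(
          feature = cl, k = kk, metric = "mismatch_rate",
          value = mean(as.character(original) != as.character(imputed)),
          n_masked = length(ridx), n_zero_excluded = 0L)
      }
    }
  }
  rep <- do.call(rbind, res)
  rownames(rep) <- NULL
  class(rep) <- c("imputation_report", "data.frame")
  rep
}

#' Write the per-feature MAPE report as CSV
#'
#' Two columns, `Feature` and `MAPE (%)`, listing the numeric features
#' for one chosen K.
#'
#' @param report An `imputation_report` from [validate_imputation()].
#' @param path Output CSV path.
#' @param k Which K to report (default: the smallest in the report).
#' @export
write_imputation_report <- function(report, path, k = min(report$k)) {
  sub <- report[report$k == k & report$metric == "mape_pct", ]
  utils::write.csv(
    data.frame(Feature = sub$feature, `MAPE (%)` = round(sub$value, 2),
               check.names = FALSE),
    path, row.names = FALSE)
  invisible(path)
}
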