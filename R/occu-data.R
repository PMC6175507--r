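#' Detection/non-detection dataset for occupancy analysis
#'
#' Bundles ragged detection histories (one row per visit to a site) with
#' site-level and visit-level covariates. Sites are surveyed a variable
#' number of times; visit rows align one-to-one with the detection record,
#' so missing visits are represented structurally rather than as sentinel
#' values.
#'
#' @param visits data frame with columns `site`, `visit`, `y` (0/1) and the
#'   visit covariates `humidity`, `temperature`, `samplingeffort`, `hour`,
#'   `rainfall`.
#' @param sites data frame with columns `site` and the site covariates
#'   `rocks`, `barerock`, `vegetation`, `siteslope`. Every site appearing in
#'   `visits` must appear here exactly once.
#' @param standardized logical; `TRUE` once covariates are on the
#'   zero-mean/unit-variance scale the model expects (see
#'   [prepare_occu_data()]).
#'
#' @return An object of class `occu_data`: a list with elements `sites`,
#'   `visits` (visit rows sorted by site then visit order) and
#'   `standardized`.
#' @seealso [read_occu_data()], [prepare_occu_data()], [simulate_study()]
#' @export
occu_data <- function(visits, sites, standardized = FALSE) {
  visits <- as.data.frame(visits)
  sites <- as.data.frame(sites)

  need_v <- c("site", "visit", "y", visit_covariate_names())
  miss <- setdiff(need_v, names(visits))
  if (length(miss) > 0)
    stop_occu("visit table is missing column(s): %s", paste(miss, collapse = ", "),
              class = "occu_missing_column")
  need_s <- c("site", site_covariate_names())
  miss <- setdiff(need_s, names(sites))
  if (length(miss) > 0)
    stop_occu("site table is missing column(s): %s", paste(miss, collapse = ", "),
              class = "occu_missing_column")

  visits$site <- as.character(visits$site)
  sites$site <- as.character(sites$site)

  if (anyDuplicated(sites$site))
    stop_occu("duplicate site id(s) in site table: %s",
              paste(unique(sites$site[duplicated(sites$site)]), collapse = ", "),
              class = "occu_duplicate_site")
  key <- paste(visits$site, visits$visit, sep = "\r")
  if (anyDuplicated(key))
    stop_occu("duplicate (site, visit) pair(s): %s",
              paste(unique(key[duplicated(key)]), collapse = "; "),
              class = "occu_duplicate_visit")
  if (!all(visits$site %in% sites$site))
    stop_occu("visit table references unknown site id(s): %s",
              paste(setdiff(visits$site, sites$site), collapse = ", "),
              class = "occu_unknown_site")
  if (!all(sites$site %in% visits$site))
    stop_occu("site(s) with no visits: %s",
              paste(setdiff(sites$site, visits$site), collapse = ", "),
              class = "occu_site_without_visits")

  for (col in c("y", visit_covariate_names())) {
    v <- visits[[col]]
    if (!is.numeric(v) && !all(!is.na(suppressWarnings(as.numeric(as.character(v))))))
      stop_occu("non-numeric values in visit column '%s'", col,
                class = "occu_nonnumeric_covariate")
    visits[[col]] <- as.numeric(as.character(v))
    if (anyNA(visits[[col]]))
      stop_occu("non-numeric or missing values in visit column '%s'", col,
                class = "occu_nonnumeric_covariate")
  }
  for (col in site_covariate_names()) {
    v <- suppressWarnings(as.numeric(as.character(sites[[col]])))
    if (anyNA(v))
      stop_occu("non-numeric or missing values in site column '%s'", col,
                class = "occu_nonnumeric_covariate")
    sites[[col]] <- v
  }
  if (!all(visits$y %in% c(0, 1)))
    stop_occu("detection values must be 0 or 1; found: %s",
              paste(unique(visits$y[!visits$y %in% c(0, 1)]), collapse = ", "),
              class = "occu_nonbinary_detection")

  # preserve site order as given in the site table; visits ordered within site
  visits$site <- factor(visits$site, levels = sites$site)
  visits <- visits[order(visits$site, visits$visit), , drop = FALSE]
  visits$site <- as.character(visits$site)
  rownames(visits) <- NULL
  rownames(sites) <- NULL

  structure(list(sites = sites, visits = visits,
                 standardized = isTRUE(standardized)),
            class = "occu_data")
}

#' @export
print.occu_data <- function(x, ...) {
  nv <- table(factor(x$visits$site, levels = x$sites$site))
  det <- tapply(x$visits$y, factor(x$visits$site, levels = x$sites$site), max)
  cat(sprintf("occupancy dataset: %d sites, %d visits (%d-%d per site)\n",
              nrow(x$sites), nrow(x$visits), min(nv), max(nv)))
  cat(sprintf("  sites with >=1 detection: %d (naive occupancy %.3f)\n",
              sum(det), mean(det)))
  cat(sprintf("  covariates standardized: %s\n", x$standardized))
  invisible(x)
}

#' Number of sites in an occupancy dataset
#' @param data an [occu_data()] object.
#' @return integer count of sites.
#' @export
n_sites <- function(data) nrow(data$sites)

# integer site index (into the site table) for each visit row
visit_site_index <- function(data) {
  match(data$visits$site, data$sites$site)
}

#' Per-site naive detection indicator
#'
#' 1 if the species was detected on at least one visit to the site, else 0.
#' @param data an [occu_data()] object.
#' @return integer vector, one element per site in site-table order.
#' @export
observed_occupancy <- function(data) {
  as.integer(tapply(data$visits$y,
                    factor(data$visits$site, levels = data$sites$site), max))
}

#' Read an occupancy dataset from visit and site tables
#'
#' Reads the two CSV files the package writes and consumes everywhere:
#' `visits.csv` with columns `site,visit,y,humidity,temperature,effort,hour,
#' rain` and `sites.csv` with columns `site,rocks,barerock,vegetation,slope`.
#' Short file column names (`effort`, `rain`, `slope`) are mapped to the
#' covariate names used internally (`samplingeffort`, `rainfall`,
#' `siteslope`).
#'
#' @param visits_path,sites_path paths to the CSV files (header row, UTF-8,
#'   site ids read as strings).
#' @param standardized logical; set `TRUE` if the files already hold
#'   standardized covariates (as those written by [write_occu_data()] after
#'   [prepare_occu_data()], or by [simulate_study()]).
#' @return An [occu_data()] object.
#' @export
read_occu_data <- function(visits_path, sites_path, standardized = FALSE) {
  visits <- read_visit_table(visits_path)
  sites <- read_site_table(sites_path)
  occu_data(visits, sites, standardized = standardized)
}

#' Read the visit-level table of a dataset
#'
#' @param path CSV file with header `site,visit,y,humidity,temperature,
#'   effort,hour,rain`.
#' @return data frame with internal column names; one row per visit, visit
#'   order preserved within site.
#' @export
read_visit_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(site = "character"))
  need <- c("site", "visit", "y", "humidity", "temperature", "effort",
            "hour", "rain")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop_occu("visit file %s is missing column(s): %s", path,
              paste(miss, collapse = ", "), class = "occu_missing_column")
  names(df)[names(df) == "effort"] <- "samplingeffort"
  names(df)[names(df) == "rain"] <- "rainfall"
  df
}

#' Read the site-level covariate table of a dataset
#'
#' @param path CSV file with header `site,rocks,barerock,vegetation,slope`.
#' @return data frame with internal column names, one row per site.
#' @export
read_site_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(site = "character"))
  need <- c("site", "rocks", "barerock", "vegetation", "slope")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop_occu("site file %s is missing column(s): %s", path,
              paste(miss, collapse = ", "), class = "occu_missing_column")
  names(df)[names(df) == "slope"] <- "siteslope"
  df
}

#' Write an occupancy dataset to the package's CSV dialect
#'
#' Inverse of [read_occu_data()]: writes `visits.csv` and `sites.csv` into
#' `dir` with the short column names (`effort`, `rain`, `slope`).
#'
#' @param data an [occu_data()] object.
#' @param dir output directory (created if absent).
#' @return Invisibly, the two file paths written.
#' @export
write_occu_data <- function(data, dir) {
  stopifnot(inherits(data, "occu_data"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  v <- data$visits
  names(v)[names(v) == "samplingeffort"] <- "effort"
  names(v)[names(v) == "rainfall"] <- "rain"
  s <- data$sites
  names(s)[names(s) == "siteslope"] <- "slope"
  vp <- file.path(dir, "visits.csv")
  sp <- file.path(dir, "sites.csv")
  utils::write.csv(v, vp, row.names = FALSE, quote = FALSE)
  utils::write.csv(s, sp, row.names = FALSE, quote = FALSE)
  invisible(c(visits = vp, sites = sp))
}

#' Scale a covariate to zero mean and unit sample variance
#'
#' Centering and scaling use the sample standard deviation (denominator
#' n - 1), the conventional choice for observed covariates; `c(1, 2, 3)`
#' maps exactly to `c(-1, 0, 1)`.
#'
#' @param values numeric vector, length at least 2.
#' @param name label used in error messages when the input is degenerate.
#' @return numeric vector of the same length with mean 0 and sample sd 1.
#' @export
standardize <- function(values, name = deparse(substitute(values))) {
  if (length(values) < 2)
    stop_occu("cannot standardize '%s': need at least 2 values", name,
              class = "occu_degenerate_covariate")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0)
    stop_occu("degenerate covariate '%s': zero sample variance", name,
              class = "occu_degenerate_covariate")
  (values - mean(values)) / s
}

#' Standardize all covariates of a dataset
#'
#' Site covariates are standardized over sites; visit covariates over the
#' pooled site-by-visit records (the scale the detection submodel sees;
#' the naive comparison model averages these standardized values per site).
#'
#' @param data an [occu_data()] object on the raw scale.
#' @return The dataset with every covariate column at mean 0 and sample
#'   sd 1, flagged `standardized = TRUE`.
#' @export
prepare_occu_data <- function(data) {
  stopifnot(inherits(data, "occu_data"))
  if (data$standardized) return(data)
  for (col in site_covariate_names())
    data$sites[[col]] <- standardize(data$sites[[col]], name = col)
  for (col in visit_covariate_names())
    data$visits[[col]] <- standardize(data$visits[[col]], name = col)
  data$standardized <- TRUE
  data
}

#' Screen covariate pairs for collinearity
#'
#' Computes the Pearson correlation for every unordered pair of columns and
#' returns the pairs at or above the threshold in absolute value. An empty
#' result means the screen passes; the conventional cutoff used here keeps
#' every pairwise |r| below 0.7.
#'
#' @param covariate_table data frame or matrix of numeric columns (at least
#'   2 columns and 3 rows).
#' @param threshold flagging threshold on |r| (default 0.7).
#' @return data frame with columns `var1`, `var2`, `r`, one row per flagged
#'   pair (zero rows when the screen passes).
#' @export
check_collinearity <- function(covariate_table, threshold = 0.7) {
  m <- as.matrix(as.data.frame(covariate_table))
  if (ncol(m) < 2 || nrow(m) < 3)
    stop_occu("collinearity screen needs >= 2 columns and >= 3 rows",
              class = "occu_bad_input")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop_occu("degenerate covariate '%s': zero sample variance",
              colnames(m)[which(sds == 0)[1]],
              class = "occu_degenerate_covariate")
  r <- stats::cor(m)
  idx <- which(upper.tri(r) & abs(r) >= threshold, arr.ind = TRUE)
  data.frame(var1 = colnames(m)[idx[, 1]],
             var2 = colnames(m)[idx[, 2]],
             r = r[idx],
             stringsAsFactors = FALSE)
}

#' Average visit covariates per site
#'
#' For each visit covariate (humidity, temperature, sampling effort, hour,
#' rainfall) returns the arithmetic mean over the site's visits. This is the
#' site-level summary consumed by the detection-ignoring comparison model;
#' the occupancy model itself uses the visit-level values directly.
#'
#' @param data an [occu_data()] object.
#' @return data frame with one row per site: `site` plus the five averaged
#'   covariates.
#' @export
average_temporal_covariates <- function(data) {
  stopifnot(inherits(data, "occu_data"))
  f <- factor(data$visits$site, levels = data$sites$site)
  out <- data.frame(site = data$sites$site, stringsAsFactors = FALSE)
  for (col in visit_covariate_names())
    out[[col]] <- as.numeric(tapply(data$visits[[col]], f, mean))
  out
}
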