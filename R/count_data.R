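#' Read raw detection records from CSV
#'
#' Parses a CSV of independent-capture candidates with columns
#' `species,unit,landscape,timestamp,count`. Timestamps must be ISO-8601
#' date-times (`YYYY-MM-DD HH:MM` or with `T` separator), interpreted
#' timezone-naive at minute resolution. The `unit` column may hold camera
#' identifiers when a camera-to-unit assignment is supplied downstream to
#' [aggregate_to_units()].
#'
#' @param path path to the records CSV.
#' @return a `data.frame` of detection records with a `POSIXct` timestamp
#'   column, validated so that every count is a positive integer and every
#'   unit maps to exactly one landscape.
#' @export
read_detection_records <- function(path) {
  if (!file.exists(path)) stop("records file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "unit", "landscape", "timestamp", "count")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("records CSV missing columns: ", paste(miss, collapse = ", "))
  df$species <- as.character(df$species)
  df$unit <- as.character(df$unit)
  df$landscape <- as.character(df$landscape)
  df$timestamp <- as.character(df$timestamp)
  df$count <- df$count
  validate_detection_records(df)
}

#' Validate a detection-record table
#'
#' @param records data.frame with columns species, unit, landscape,
#'   timestamp, count.
#' @return the validated records with timestamp converted to `POSIXct`
#'   (UTC, minute resolution) and rows ordered by species, unit, time.
#' @export
validate_detection_records <- function(records) {
  if (nrow(records) == 0) {
    records$timestamp <- as.POSIXct(character(0), tz = "UTC")
    return(records)
  }
  if (!inherits(records$timestamp, "POSIXct")) {
    raw <- gsub("T", " ", as.character(records$timestamp))
    ts <- as.POSIXct(rep(NA_real_, length(raw)), origin = "1970-01-01",
                     tz = "UTC")
    for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
      idx <- is.na(ts)
      if (!any(idx)) break
      ts[idx] <- as.POSIXct(strptime(raw[idx], fmt, tz = "UTC"))
    }
    bad <- which(is.na(ts))
    if (length(bad)) {
      stop("unparseable timestamp in record(s) ",
           paste(utils::head(bad, 5L), collapse = ", "),
           " (value '", records$timestamp[bad[1L]], "')")
    }
    records$timestamp <- ts
  }
  if (any(is.na(records$count)) || any(records$count < 1) ||
      any(records$count != round(records$count))) {
    stop("record counts must be integers >= 1")
  }
  records$count <- as.integer(records$count)
  # each sampling location must belong to exactly one landscape
  map <- unique(records[, c("unit", "landscape")])
  dup <- map$unit[duplicated(map$unit)]
  if (length(dup)) {
    stop("unit(s) mapped to more than one landscape: ",
         paste(unique(dup), collapse = ", "))
  }
  records[order(records$species, records$unit, records$timestamp), ,
          drop = FALSE]
}

#' Filter captures to temporal independence
#'
#' Applies the anchored independence rule used in camera-trap studies:
#' within each species-by-location stream (ordered by time), a capture is
#' retained if and only if it occurred at least `window_minutes` after the
#' last *retained* capture. Ties at exactly the window are kept. Counts of
#' suppressed captures are discarded, not added to the survivors.
#'
#' The operation is idempotent: filtering an already-filtered stream
#' changes nothing.
#'
#' @param records detection records (see [read_detection_records()]).
#' @param window_minutes minimum separation in minutes (default 30).
#' @return the retained subset of `records`, ordered by species, unit,
#'   time.
#' @export
filter_independent_captures <- function(records, window_minutes = 30) {
  stopifnot(window_minutes >= 0)
  records <- validate_detection_records(records)
  if (nrow(records) == 0) return(records)
  keep <- logical(nrow(records))
  key <- paste(records$species, records$unit, sep = "\r")
  for (idx in split(seq_len(nrow(records)), key)) {
    last_kept <- -Inf
    tt <- as.numeric(records$timestamp[idx]) / 60  # minutes
    for (q in seq_along(idx)) {
      if (tt[q] - last_kept >= window_minutes) {
        keep[idx[q]] <- TRUE
        last_kept <- tt[q]
      }
    }
  }
  records[keep, , drop = FALSE]
}

#' Aggregate filtered captures to sampling units and days
#'
#' Pools cameras into sampling units (averaging their covariates) and sums
#' the individuals observed per species, unit, and calendar day. Days on
#' which a unit had no active camera are flagged unobserved rather than
#' zero-filled.
#'
#' @param records filtered detection records. When `unit_assignment` is
#'   supplied, the `unit` column of `records` is interpreted as a *camera*
#'   identifier and mapped through the assignment; otherwise records are
#'   taken to be keyed by sampling unit already.
#' @param unit_assignment optional data.frame with columns `camera`,
#'   `unit` and optionally `landscape`. Every camera appearing in
#'   `records` must be listed; unknown cameras are an error naming them.
#' @param camera_covariates optional data.frame whose first column is the
#'   camera (or unit, when no assignment is given) identifier, remaining
#'   numeric columns are covariates; the unit value is the arithmetic mean
#'   over its cameras.
#' @param camera_activity optional data.frame `camera,start,end` (dates)
#'   giving each camera's deployment window. Defaults to every camera
#'   active over the full span of the record timestamps; effort in trap
#'   nights is the sum of active camera-days per unit.
#' @param species optional character vector fixing the species dimension
#'   (useful to retain a species with zero captures); defaults to the
#'   species observed.
#' @return an object of class `daily_counts`: counts array
#'   `[species, unit, day]`, logical `sampled[unit, day]` matrix, dates,
#'   per-unit landscape, trap-night effort, and averaged covariates.
#' @export
aggregate_to_units <- function(records, unit_assignment = NULL,
                               camera_covariates = NULL,
                               camera_activity = NULL,
                               species = NULL) {
  records <- validate_detection_records(records)
  if (!is.null(unit_assignment)) {
    stopifnot(all(c("camera", "unit") %in% names(unit_assignment)))
    unit_assignment$camera <- as.character(unit_assignment$camera)
    unit_assignment$unit <- as.character(unit_assignment$unit)
    unknown <- setdiff(unique(records$unit), unit_assignment$camera)
    if (length(unknown)) {
      stop("camera(s) missing from unit assignment: ",
           paste(unknown, collapse = ", "))
    }
    cam2unit <- stats::setNames(unit_assignment$unit, unit_assignment$camera)
    records$camera <- records$unit
    records$unit <- unname(cam2unit[records$camera])
    units <- sort(unique(unit_assignment$unit))
    if ("landscape" %in% names(unit_assignment)) {
      u2l <- unique(unit_assignment[, c("unit", "landscape")])
      if (anyDuplicated(u2l$unit)) stop("unit assigned to multiple landscapes")
      landscape <- stats::setNames(as.character(u2l$landscape), u2l$unit)[units]
    } else {
      u2l <- unique(records[, c("unit", "landscape")])
      landscape <- stats::setNames(u2l$landscape, u2l$unit)[units]
    }
    cams_of <- split(unit_assignment$camera, unit_assignment$unit)
  } else {
    records$camera <- records$unit
    units <- sort(unique(records$unit))
    u2l <- unique(records[, c("unit", "landscape")])
    landscape <- stats::setNames(u2l$landscape, u2l$unit)[units]
    cams_of <- as.list(stats::setNames(units, units))
  }
  if (is.null(species)) species <- sort(unique(records$species))
  if (nrow(records) == 0 && length(species) == 0) {
    stop("no records and no species given: nothing to aggregate")
  }

  # sampling calendar
  if (!is.null(camera_activity)) {
    stopifnot(all(c("camera", "start", "end") %in% names(camera_activity)))
    camera_activity$camera <- as.character(camera_activity$camera)
    act_start <- as.Date(camera_activity$start)
    act_end <- as.Date(camera_activity$end)
    if (any(act_end < act_start)) stop("camera_activity: end before start")
    dates <- seq(min(act_start), max(act_end), by = "day")
  } else {
    if (nrow(records) == 0) stop("cannot infer sampling dates from zero records; supply camera_activity")
    dr <- as.Date(records$timestamp)
    dates <- seq(min(dr), max(dr), by = "day")
  }
  J <- length(units); D <- length(dates); S <- length(species)
  sampled <- matrix(FALSE, J, D, dimnames = list(units, as.character(dates)))
  trap_nights <- stats::setNames(numeric(J), units)
  for (j in seq_len(J)) {
    for (cam in cams_of[[units[j]]]) {
      if (!is.null(camera_activity)) {
        rows <- which(camera_activity$camera == cam)
        for (rr in rows) {
          on <- dates >= act_start[rr] & dates <= act_end[rr]
          sampled[j, on] <- TRUE
          trap_nights[j] <- trap_nights[j] + sum(on)
        }
      } else {
        sampled[j, ] <- TRUE
        trap_nights[j] <- trap_nights[j] + D
      }
    }
  }

  counts <- array(0L, c(S, J, D), dimnames = list(species, units,
                                                  as.character(dates)))
  if (nrow(records)) {
    day <- as.character(as.Date(records$timestamp))
    ok <- records$species %in% species & day %in% as.character(dates)
    rec <- records[ok, , drop = FALSE]
    day <- day[ok]
    if (nrow(rec)) {
      tab <- tapply(rec$count,
                    list(factor(rec$species, species),
                         factor(rec$unit, units),
                         factor(day, as.character(dates))),
                    sum)
      tab[is.na(tab)] <- 0L
      counts[] <- as.integer(tab)
    }
  }

  covariates <- NULL
  if (!is.null(camera_covariates)) {
    idcol <- names(camera_covariates)[1L]
    ids <- as.character(camera_covariates[[idcol]])
    vals <- as.matrix(camera_covariates[, -1L, drop = FALSE])
    covariates <- matrix(NA_real_, J, ncol(vals),
                         dimnames = list(units, colnames(vals)))
    for (j in seq_len(J)) {
      rows <- which(ids %in% cams_of[[units[j]]])
      if (length(rows)) covariates[j, ] <- colMeans(vals[rows, , drop = FALSE])
    }
  }

  structure(list(counts = counts, sampled = sampled, dates = dates,
                 species = species, units = units,
                 landscape = as.character(landscape),
                 trap_nights = trap_nights, covariates = covariates),
            class = "daily_counts")
}

#' Cap daily counts at one group
#'
#' For gregarious species counted as groups rather than individuals, each
#' daily observation is limited to zero or one group before occasion
#' binning; other species are untouched. Idempotent.
#'
#' @param daily a `daily_counts` object.
#' @param species the species whose counts are capped.
#' @return the modified `daily_counts`.
#' @export
cap_group_counts <- function(daily, species) {
  stopifnot(inherits(daily, "daily_counts"))
  i <- match(species, daily$species)
  if (is.na(i)) stop("unknown species: ", species)
  daily$counts[i, , ] <- pmin(daily$counts[i, , ], 1L)
  daily
}

#' Bin daily counts into sampling occasions
#'
#' Sums daily counts into consecutive blocks of `occasion_days` days. A
#' trailing partial block is retained as a (shorter) occasion; the
#' trap-night effort per unit carries the amount of sampling into the
#' detection model. An occasion is considered observed for a unit if the
#' unit was sampled on at least one day of the block.
#'
#' @param daily a `daily_counts` object.
#' @param occasion_days days pooled per occasion (default 5).
#' @return a [count_history()] object.
#' @export
bin_occasions <- function(daily, occasion_days = 5) {
  stopifnot(inherits(daily, "daily_counts"), occasion_days >= 1)
  if (any(daily$counts < 0)) stop("negative daily counts")
  D <- dim(daily$counts)[3L]
  S <- dim(daily$counts)[1L]; J <- dim(daily$counts)[2L]
  blocks <- split(seq_len(D), ceiling(seq_len(D) / occasion_days))
  O <- length(blocks)
  counts <- array(0L, c(S, J, O),
                  dimnames = list(daily$species, daily$units, NULL))
  mask <- array(FALSE, c(S, J, O))
  for (o in seq_len(O)) {
    dd <- blocks[[o]]
    sampled_o <- rowSums(daily$sampled[, dd, drop = FALSE]) > 0
    for (s in seq_len(S)) {
      sl <- daily$counts[s, , dd, drop = FALSE]
      dim(sl) <- c(J, length(dd))
      # unsampled days hold structural zeros; summing them adds nothing
      counts[s, , o] <- as.integer(rowSums(sl))
      mask[s, , o] <- sampled_o
    }
  }
  count_history(counts, mask, occasion_days = as.integer(occasion_days),
                effort = daily$trap_nights, species = daily$species,
                units = daily$units, landscape = daily$landscape,
                covariates = daily$covariates)
}

#' Construct a count history
#'
#' The central data container: integer counts per species, sampling unit,
#' and occasion, with an observation mask and per-unit trap-night effort.
#' Counts at masked-out cells are ignored by all likelihoods.
#'
#' @param counts integer array `[species, unit, occasion]`, >= 0 where
#'   observed.
#' @param mask logical array of the same shape; `TRUE` means observed.
#' @param occasion_days days per occasion.
#' @param effort trap nights per unit (non-negative).
#' @param species,units,landscape identifiers (landscape one per unit).
#' @param covariates optional numeric matrix `[unit, covariate]` of raw
#'   (unstandardized) site covariates.
#' @return object of class `count_history`.
#' @export
count_history <- function(counts, mask = NULL, occasion_days = 5L,
                          effort = NULL, species = NULL, units = NULL,
                          landscape = NULL, covariates = NULL) {
  counts <- as.array(counts)
  stopifnot(length(dim(counts)) == 3L)
  S <- dim(counts)[1L]; J <- dim(counts)[2L]; O <- dim(counts)[3L]
  if (is.null(mask)) mask <- array(TRUE, dim(counts))
  mask <- array(as.logical(mask), dim(counts))
  if (occasion_days < 1) stop("occasion_days must be >= 1")
  if (any(counts[mask] < 0, na.rm = TRUE)) stop("observed counts must be >= 0")
  counts[!mask] <- 0L
  if (is.null(effort)) effort <- rep(occasion_days * O, J)
  if (length(effort) != J || any(effort < 0)) stop("effort must be non-negative, one per unit")
  if (is.null(species)) species <- dimnames(counts)[[1L]] %||% paste0("sp", seq_len(S))
  if (is.null(units)) units <- dimnames(counts)[[2L]] %||% paste0("u", seq_len(J))
  if (is.null(landscape)) landscape <- rep("L1", J)
  stopifnot(length(species) == S, length(units) == J, length(landscape) == J)
  dimnames(counts) <- list(species, units, NULL)
  structure(list(counts = counts, mask = mask,
                 occasion_days = as.integer(occasion_days),
                 effort = stats::setNames(as.numeric(effort), units),
                 species = species,
                 units = units, landscape = as.character(landscape),
                 covariates = covariates),
            class = "count_history")
}

#' @export
print.count_history <- function(x, ...) {
  d <- dim(x$counts)
  cat("count_history:", d[1L], "species x", d[2L], "units x", d[3L],
      "occasions of", x$occasion_days, "days\n")
  cat("  total counts:",
      paste(x$species, apply(x$counts, 1L, sum), sep = "=", collapse = ", "),
      "\n")
  cat("  observed cells:", sum(x$mask), "/", length(x$mask),
      "; trap nights:", sum(x$effort), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standardize site covariates and screen collinearity
#'
#' Centers and scales every numeric covariate to mean 0, SD 1 (sample SD,
#' denominator n-1), and checks all pairwise Pearson correlations; any
#' pair with |r| >= `r_max` is an error reporting the pair. Effort is
#' standardized the same way for the detection model.
#'
#' @param raw numeric matrix or data.frame `[unit, covariate]` with >= 2
#'   units.
#' @param landscape character/factor of landscape membership per unit.
#' @param effort trap nights per unit.
#' @param r_max collinearity threshold on |Pearson r| (default 0.5).
#' @return object of class `site_covariates` with fields `values`
#'   (standardized matrix), `names`, `landscape_index`,
#'   `landscape_names`, `effort_std`, `effort`.
#' @export
standardize_covariates <- function(raw, landscape = NULL, effort = NULL,
                                   r_max = 0.5) {
  x <- as.matrix(raw)
  storage.mode(x) <- "double"
  if (nrow(x) < 2L) stop("need >= 2 units to standardize")
  if (is.null(colnames(x))) colnames(x) <- paste0("cov", seq_len(ncol(x)))
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    stop("zero-variance covariate column(s): ",
         paste(colnames(x)[sds == 0 | !is.finite(sds)], collapse = ", "))
  }
  z <- scale(x)  # sample SD, n-1
  attr(z, "scaled:center") <- NULL; attr(z, "scaled:scale") <- NULL
  if (ncol(z) >= 2L) {
    r <- stats::cor(z)
    for (a in seq_len(ncol(z) - 1L)) for (b in (a + 1L):ncol(z)) {
      if (abs(r[a, b]) >= r_max) {
        stop(sprintf("collinearity: |r(%s, %s)| = %.3f >= %.2f",
                     colnames(z)[a], colnames(z)[b], abs(r[a, b]), r_max))
      }
    }
  }
  if (is.null(landscape)) landscape <- rep("L1", nrow(x))
  lnames <- unique(as.character(landscape))
  lidx <- match(as.character(landscape), lnames)
  if (is.null(effort)) effort <- rep(1, nrow(x))
  es <- if (stats::sd(effort) > 0) as.numeric(scale(effort)) else rep(0, length(effort))
  structure(list(values = z, names = colnames(z), landscape_index = lidx,
                 landscape_names = lnames, effort_std = es,
                 effort = as.numeric(effort)),
            class = "site_covariates")
}

#' Build the informed zero-inflation indicator
#'
#' Classifies true zeros: Z[i,j] = 1 whenever unit j lies in a landscape
#' where species i was detected at least once, and 0 only where the
#' species was never detected in the landscape *and* the caller supplies a
#' corroborated extirpation flag for that (species, landscape) pair. A
#' flag contradicting a detection is an error, which prevents fixing
#' abundance to zero where the species was seen.
#'
#' @param history a `count_history`.
#' @param landscape_index landscape membership per unit (defaults to the
#'   history's own landscape labels).
#' @param extirpation_flags data.frame with columns `species`,
#'   `landscape` (may be empty or NULL for no known extirpations).
#' @return object of class `zero_informant` holding the binary matrix
#'   `Z[species, unit]`.
#' @export
build_zero_informant <- function(history, landscape_index = NULL,
                                 extirpation_flags = NULL) {
  stopifnot(inherits(history, "count_history"))
  land <- as.character(landscape_index %||% history$landscape)
  stopifnot(length(land) == length(history$units))
  S <- length(history$species)
  det <- matrix(0, S, length(unique(land)),
                dimnames = list(history$species, unique(land)))
  obs <- history$counts; obs[!history$mask] <- 0L
  for (s in seq_len(S)) {
    per_unit <- rowSums(matrix(obs[s, , ], nrow = dim(obs)[2L]))
    det[s, ] <- tapply(per_unit, factor(land, colnames(det)), sum)
  }
  Z <- matrix(1L, S, length(history$units),
              dimnames = list(history$species, history$units))
  if (!is.null(extirpation_flags) && nrow(extirpation_flags)) {
    for (rr in seq_len(nrow(extirpation_flags))) {
      sp <- as.character(extirpation_flags$species[rr])
      la <- as.character(extirpation_flags$landscape[rr])
      if (!sp %in% history$species) stop("extirpation flag for unknown species: ", sp)
      if (!la %in% colnames(det)) stop("extirpation flag for unknown landscape: ", la)
      if (det[sp, la] > 0) {
        stop(sprintf("extirpation flag (%s, %s) contradicts %d detected individuals",
                     sp, la, det[sp, la]))
      }
      Z[sp, land == la] <- 0L
    }
  }
  structure(list(Z = Z, species = history$species, units = history$units),
            class = "zero_informant")
}

#' Bundle a count history, covariates, and zero informant
#'
#' Validates mutual consistency (dimensions, unit order, Z = 0 only where
#' no detections) and returns the data object every model-fitting function
#' consumes. Exactly two species are required: the first is the dominant,
#' the second the subordinate.
#'
#' @param history `count_history` with 2 species.
#' @param covariates `site_covariates` for the same units.
#' @param informant `zero_informant`; defaults to Z = 1 everywhere (no
#'   known extirpations), under which the iZIP reduces to a plain Poisson
#'   mixture.
#' @return object of class `coabund_data`.
#' @export
coabund_data <- function(history, covariates, informant = NULL) {
  stopifnot(inherits(history, "count_history"),
            inherits(covariates, "site_covariates"))
  S <- dim(history$counts)[1L]; J <- dim(history$counts)[2L]
  if (S != 2L) stop("co-abundance model requires exactly 2 species (dominant, subordinate)")
  if (nrow(covariates$values) != J) stop("covariates/history unit mismatch")
  if (length(covariates$landscape_index) != J) stop("landscape index length mismatch")
  if (is.null(informant)) {
    informant <- structure(list(Z = matrix(1L, S, J), species = history$species,
                                units = history$units),
                           class = "zero_informant")
  }
  stopifnot(inherits(informant, "zero_informant"),
            all(dim(informant$Z) == c(S, J)))
  obs <- history$counts; obs[!history$mask] <- 0L
  for (s in seq_len(S)) {
    bad <- informant$Z[s, ] == 0 & rowSums(matrix(obs[s, , ], nrow = J)) > 0
    if (any(bad)) {
      stop("zero informant contradicts detections for species ",
           history$species[s], " at unit(s) ",
           paste(history$units[bad], collapse = ", "))
    }
  }
  structure(list(history = history, covariates = covariates,
                 informant = informant),
            class = "coabund_data")
}

#' @export
print.coabund_data <- function(x, ...) {
  print(x$history)
  cat("  covariates:", paste(x$covariates$names, collapse = ", "),
      "| landscapes:", length(x$covariates$landscape_names), "\n")
  cat("  Z=0 units:",
      paste(x$history$species, rowSums(1 - x$informant$Z), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}
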