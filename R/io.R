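#' Write a count-history bundle to a directory
#'
#' Three CSVs: `counts.csv` (long form `species,unit,occasion,count,mask`),
#' `units.csv` (`unit,landscape,effort` plus raw covariate columns), and
#' `flags.csv` (`species,landscape` extirpation flags implied by the zero
#' informant). [read_bundle()] round-trips the result.
#'
#' @param data a `coabund_data` (or `coabund_sim`, whose truth table is
#'   then written as `truth.csv` too).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(data, dir) {
  truth <- NULL
  if (inherits(data, "coabund_sim")) {
    truth <- data$truth
    data <- data$data
  }
  stopifnot(inherits(data, "coabund_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hist <- data$history
  S <- dim(hist$counts)[1L]; J <- dim(hist$counts)[2L]
  O <- dim(hist$counts)[3L]
  long <- expand.grid(occasion = seq_len(O), unit = hist$units,
                      species = hist$species, stringsAsFactors = FALSE)
  long <- long[, c("species", "unit", "occasion")]
  long$count <- as.integer(aperm(hist$counts, c(3L, 2L, 1L)))
  long$mask <- as.integer(aperm(hist$mask, c(3L, 2L, 1L)))
  utils::write.csv(long, file.path(dir, "counts.csv"), row.names = FALSE)

  raw <- hist$covariates
  if (is.null(raw)) raw <- data$covariates$values  # already standardized
  units_df <- data.frame(unit = hist$units, landscape = hist$landscape,
                         effort = hist$effort, stringsAsFactors = FALSE)
  units_df <- cbind(units_df, as.data.frame(raw))
  utils::write.csv(units_df, file.path(dir, "units.csv"), row.names = FALSE)

  Z <- data$informant$Z
  flags <- NULL
  for (i in seq_len(S)) {
    for (l in unique(hist$landscape)) {
      zz <- Z[i, hist$landscape == l]
      if (all(zz == 0L)) {
        flags <- rbind(flags, data.frame(species = hist$species[i],
                                         landscape = l,
                                         stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(flags)) {
    flags <- data.frame(species = character(0), landscape = character(0))
  }
  utils::write.csv(flags, file.path(dir, "flags.csv"), row.names = FALSE)

  if (!is.null(truth)) {
    tp <- truth$params
    covn <- data$covariates$names
    tr <- rbind(
      data.frame(parameter = sprintf("alpha0[%s]", sp_labels), value = tp$alpha0),
      data.frame(parameter = as.vector(t(outer(sp_labels, covn,
                   function(a, b) sprintf("alpha_%s[%s]", b, a)))),
                 value = as.numeric(t(tp$alpha))),
      data.frame(parameter = "delta", value = tp$delta),
      data.frame(parameter = sprintf("beta0[%s]", sp_labels), value = tp$beta0),
      data.frame(parameter = sprintf("beta1[%s]", sp_labels), value = tp$beta1),
      data.frame(parameter = sprintf("tau[%s]", sp_labels), value = tp$tau),
      data.frame(parameter = sprintf("sigma_land[%s]", sp_labels),
                 value = tp$sigma_land))
    utils::write.csv(tr, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a count-history bundle
#'
#' Reads the CSVs written by [write_bundle()] (or prepared by hand in the
#' same layout), standardizes the covariates, rebuilds the zero
#' informant from the flags, and validates the result.
#'
#' @param dir bundle directory.
#' @return a `coabund_data`.
#' @export
read_bundle <- function(dir) {
  for (f in c("counts.csv", "units.csv")) {
    if (!file.exists(file.path(dir, f))) stop("bundle missing ", f, " in ", dir)
  }
  long <- utils::read.csv(file.path(dir, "counts.csv"),
                          stringsAsFactors = FALSE)
  units_df <- utils::read.csv(file.path(dir, "units.csv"),
                              stringsAsFactors = FALSE)
  species <- unique(long$species)
  units <- units_df$unit
  O <- max(long$occasion)
  S <- length(species); J <- length(units)
  counts <- array(0L, c(S, J, O), dimnames = list(species, units, NULL))
  mask <- array(FALSE, c(S, J, O))
  si <- match(long$species, species); ui <- match(long$unit, units)
  if (anyNA(ui)) stop("counts.csv refers to units absent from units.csv")
  idx <- cbind(si, ui, long$occasion)
  counts[idx] <- as.integer(long$count)
  mask[idx] <- as.logical(long$mask)
  covcols <- setdiff(names(units_df), c("unit", "landscape", "effort"))
  raw <- as.matrix(units_df[, covcols, drop = FALSE])
  rownames(raw) <- units
  hist <- count_history(counts, mask, effort = units_df$effort,
                        species = species, units = units,
                        landscape = units_df$landscape, covariates = raw)
  covs <- standardize_covariates(raw, landscape = units_df$landscape,
                                 effort = units_df$effort)
  flags_path <- file.path(dir, "flags.csv")
  flags <- if (file.exists(flags_path)) {
    utils::read.csv(flags_path, stringsAsFactors = FALSE)
  } else NULL
  if (!is.null(flags) && nrow(flags) == 0L) flags <- NULL
  informant <- build_zero_informant(hist, extirpation_flags = flags)
  coabund_data(hist, covs, informant)
}

#' Write posterior draws of the model parameters to CSV
#'
#' Columnar layout: `chain`, `draw`, one column per (non-latent) model
#' parameter.
#'
#' @param fit a `coabund_fit`.
#' @param path output CSV.
#' @export
write_draws <- function(fit, path) {
  top <- fit$par_names[seq_len(fit$n_top)]
  pool <- pool_draws(fit)[, top, drop = FALSE]
  d <- dim(fit$draws)
  out <- data.frame(chain = rep(seq_len(d[2L]), each = d[1L]),
                    draw = rep(seq_len(d[1L]), times = d[2L]))
  out <- cbind(out, as.data.frame(pool))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
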