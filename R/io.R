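#' Read a signal-track file
#'
#' Reads a tab-delimited track with header `chrom  pos  value`. Positions must
#' be strictly increasing within each chromosome; duplicated or unsorted
#' positions are an error naming the offending lines. Chromosome order is
#' preserved as first seen.
#'
#' @param path File path.
#' @return Tibble with columns `chrom` (character), `pos`, `value`.
#' @export
read_signal_tracks <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(),
    pos = readr::col_double(),
    value = readr::col_double()
  ), progress = FALSE)
  if (!all(c("chrom", "pos", "value") %in% names(df))) {
    stop("expected header 'chrom\tpos\tvalue' in ", path)
  }
  for (ch in unique(df$chrom)) {
    i <- which(df$chrom == ch)
    bad <- i[which(diff(df$pos[i]) <= 0) + 1L]
    if (length(bad) > 0L) {
      stop("unsorted or duplicated positions on chromosome ", ch,
           " at line(s) ", paste(bad + 1L, collapse = ", "), " of ", path)
    }
  }
  df
}

#' Write a signal track
#'
#' @param track Tibble with columns `chrom`, `pos`, `value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_tracks <- function(track, path) {
  stopifnot(all(c("chrom", "pos", "value") %in% names(track)))
  readr::write_tsv(track[, c("chrom", "pos", "value")], path, progress = FALSE)
  invisible(path)
}

#' Read a recombination-map interval file
#'
#' Tab-delimited with header `chrom  start  end  rate`. Rate units (Morgans/bp,
#' cM/Mb, or population-scaled rho) are declared by the caller wherever the
#' map is used.
#'
#' @param path File path.
#' @return Tibble `chrom`, `start`, `end`, `rate`.
#' @export
read_recombination_map <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(),
    start = readr::col_double(),
    end = readr::col_double(),
    rate = readr::col_double()
  ), progress = FALSE)
  if (any(df$rate < 0)) stop("negative recombination rate in ", path)
  df
}

#' Read a genotype-posterior track
#'
#' Tab-delimited with header `chrom  pos  pAA  pAa  paa`.
#'
#' @param path File path.
#' @return Tibble suitable for [diploid_dosage()].
#' @export
read_posterior_tracks <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(),
    pos = readr::col_double(),
    pAA = readr::col_double(),
    pAa = readr::col_double(),
    paa = readr::col_double()
  ), progress = FALSE)
}

# Shared: write a decomposition tibble in the canonical on-disk layout
# `scale statistic value contribution n_chrom ci_lo ci_hi` and a provenance
# record (config + seed + package version) alongside it.
.write_decomp <- function(decomp, path, config) {
  statistic <- attr(decomp, "statistic")
  value <- if (statistic == "variance") decomp$variance else decomp$correlation
  out <- tibble::tibble(
    scale = decomp$scale,
    scale_map_units = decomp$scale_map,
    statistic = statistic,
    value = value,
    contribution = decomp$contribution,
    n_chrom = decomp$n_chrom,
    ci_lo = decomp$ci_lo,
    ci_hi = decomp$ci_hi
  )
  readr::write_tsv(out, path, progress = FALSE)
  prov <- list(
    config = config[!vapply(config, is.null, logical(1))],
    package = "admixwave",
    version = as.character(utils::packageVersion("admixwave"))
  )
  jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run a genome-wide variance decomposition from files
#'
#' Composes track reading, optional gridding, the Haar MODWT, and the
#' genome-wide variance decomposition, writing a tab-delimited result table
#' (`scale  scale_map_units  statistic  value  contribution  n_chrom  ci_lo
#' ci_hi`) plus a machine-readable provenance record.
#'
#' @param config Named list: `input` (signal-track path), `output` (table
#'   path); optional `resolution` (grid step; if given the track is
#'   interpolated first), `interp` (`"linear"` or `"step"`), `estimator`,
#'   `jackknife_level`, `seed`.
#' @return The output path, invisibly.
#' @export
run_vardecomp <- function(config) {
  stopifnot(!is.null(config$input), !is.null(config$output))
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  sig <- read_signal_tracks(config$input)
  if (!is.null(config$resolution)) {
    sig <- interpolate_to_grid(sig, as.numeric(config$resolution),
                               method = config$interp %||% "linear")
  }
  dec <- gnom_var_decomp(sig,
                         estimator = config$estimator %||% "unbiased",
                         conf_level = as.numeric(config$jackknife_level %||% 0.95))
  .write_decomp(dec, config$output, config)
}

#' Run a genome-wide correlation decomposition from files
#'
#' As [run_vardecomp()] for two signals; `config$input` and `config$input2`
#' name the two tracks. If `config$predictors` (a character vector of track
#' paths) is supplied, a per-scale variance-explained regression table is also
#' written to `<output>.r2.tsv` using those tracks as predictors of the first
#' signal.
#'
#' @param config Named list as in [run_vardecomp()] plus `input2` and optional
#'   `predictors`.
#' @return The output path, invisibly.
#' @export
run_cordecomp <- function(config) {
  stopifnot(!is.null(config$input), !is.null(config$input2), !is.null(config$output))
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  if (!file.exists(config$input2)) stop("input2 not found: ", config$input2)
  x <- read_signal_tracks(config$input)
  y <- read_signal_tracks(config$input2)
  if (!is.null(config$resolution)) {
    res <- as.numeric(config$resolution)
    meth <- config$interp %||% "linear"
    x <- interpolate_to_grid(x, res, method = meth)
    y <- interpolate_to_grid(y, res, method = meth)
  }
  dec <- gnom_cor_decomp(x, y,
                         estimator = config$estimator %||% "unbiased",
                         conf_level = as.numeric(config$jackknife_level %||% 0.95))
  .write_decomp(dec, config$output, config)
  if (!is.null(config$predictors)) {
    preds <- lapply(config$predictors, function(p) {
      tr <- read_signal_tracks(p)
      if (!is.null(config$resolution)) {
        tr <- interpolate_to_grid(tr, as.numeric(config$resolution),
                                  method = config$interp %||% "linear")
      }
      tr
    })
    r2 <- variance_explained_by_predictor(x, preds,
                                          estimator = config$estimator %||% "unbiased")
    readr::write_tsv(r2, paste0(config$output, ".r2.tsv"), progress = FALSE)
  }
  invisible(config$output)
}

#' Read a key-value run configuration file
#'
#' Parses a plain-text configuration in Debian-control (`key: value`) format,
#' mirroring the command-line flags of the `admixwave` script. Comma-separated
#' values become vectors; numeric-looking values are left as strings for the
#' consumer to coerce.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  m <- read.dcf(path)
  cfg <- as.list(m[1, ])
  lapply(cfg, function(v) {
    parts <- trimws(strsplit(v, ",")[[1]])
    if (length(parts) > 1L) parts else v
  })
}
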