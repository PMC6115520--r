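# Tabular I/O for measurements, rates and ratio constraints, plus the
# correction stage applied to raw measurement tables.

#' Write a measurement set to TSV files
#'
#' Writes \code{measurements.tsv} (tracer, fragment, mass, value, sd),
#' \code{rates.tsv} (reaction, value, sd) and, when present,
#' \code{ratios.tsv} (branch, num, den, value, sd) into \code{dir}.
#'
#' @param meas A \code{measurement_set}.
#' @param dir Output directory (created if needed).
#' @param format Either \code{"fractions"} (values are MDV fractions) or
#'   \code{"intensities"}; recorded in the file header.
#' @return Invisibly, the paths written.
#' @export
write_measurements <- function(meas, dir, format = "fractions") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mpath <- file.path(dir, "measurements.tsv")
  con <- file(mpath, "w")
  writeLines(paste0("# format: ", format), con)
  utils::write.table(fmt_num_df(meas$mdv), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  paths <- mpath
  if (!is.null(meas$rates) && nrow(meas$rates)) {
    rpath <- file.path(dir, "rates.tsv")
    utils::write.table(fmt_num_df(meas$rates), rpath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, rpath)
  }
  if (!is.null(meas$ratios) && nrow(meas$ratios)) {
    qpath <- file.path(dir, "ratios.tsv")
    utils::write.table(fmt_num_df(meas$ratios), qpath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, qpath)
  }
  invisible(paths)
}

# stable numeric formatting so identical inputs give byte-identical files
fmt_num_df <- function(d) {
  for (cn in names(d)) {
    if (is.numeric(d[[cn]])) d[[cn]] <- formatC(d[[cn]], digits = 12,
                                                format = "g")
  }
  d
}

#' Read a measurement set from TSV files
#'
#' @param dir Directory containing \code{measurements.tsv} and optionally
#'   \code{rates.tsv} / \code{ratios.tsv} (see
#'   \code{\link{write_measurements}}).
#' @return List with the \code{measurement_set} and the declared
#'   \code{format} ("fractions" or "intensities").
#' @export
read_measurements <- function(dir) {
  mpath <- file.path(dir, "measurements.tsv")
  if (!file.exists(mpath)) stop("measurement file not found: ", mpath)
  first <- readLines(mpath, n = 1)
  format <- if (grepl("^#\\s*format:", first)) {
    trimws(sub("^#\\s*format:", "", first))
  } else "fractions"
  mdv <- utils::read.delim(mpath, comment.char = "#")
  rates <- NULL
  rpath <- file.path(dir, "rates.tsv")
  if (file.exists(rpath)) rates <- utils::read.delim(rpath, comment.char = "#")
  ratios <- NULL
  qpath <- file.path(dir, "ratios.tsv")
  if (file.exists(qpath)) ratios <- utils::read.delim(qpath, comment.char = "#")
  list(measurements = measurement_set(mdv, rates, ratios), format = format)
}

#' Normalize and natural-abundance-correct a raw measurement table
#'
#' Applies the processing chain to every fragment in a measurement set:
#' intensity normalization (when the data are raw intensities),
#' natural-abundance correction with the fragment's non-skeleton formula,
#' and truncation to the skeleton carbon count.
#'
#' @param meas A \code{measurement_set} whose mdv table covers masses
#'   0..window per fragment.
#' @param fragments Fragment table supplying carbon sets and formulas.
#' @param format \code{"intensities"} or \code{"fractions"}.
#' @param elements Elements corrected (default C, H, O; see
#'   \code{\link{build_correction_matrix}}).
#' @param correct Apply natural-abundance correction (set FALSE when the
#'   data were generated without natural abundance).
#' @return A corrected \code{measurement_set} with masses 0..n per fragment.
#' @export
process_measurements <- function(meas, fragments, format = "fractions",
                                 elements = c("C", "H", "O"),
                                 correct = TRUE) {
  out <- list()
  for (key in unique(paste(meas$mdv$tracer, meas$mdv$fragment, sep = "\r"))) {
    parts <- strsplit(key, "\r")[[1]]
    g <- meas$mdv[meas$mdv$tracer == parts[1] & meas$mdv$fragment == parts[2], ]
    g <- g[order(g$mass), ]
    fi <- match(parts[2], fragments$fragment)
    if (is.na(fi)) stop("fragment not in fragment table: ", parts[2])
    n <- length(parse_carbon_set(fragments$carbon_set[fi]))
    vals <- g$value
    if (format == "intensities") vals <- normalize_intensities(vals)
    if (correct) {
      C <- build_correction_matrix(fragments$formula[fi], n,
                                   window = length(vals) - 1L,
                                   elements = elements)
      vals <- correct_mdv(vals, C)
    } else {
      vals <- vals[seq_len(n + 1L)]
      vals <- vals / sum(vals)
    }
    out[[key]] <- data.frame(tracer = parts[1], fragment = parts[2],
                             mass = seq_along(vals) - 1L, value = vals,
                             sd = g$sd[seq_along(vals)])
  }
  measurement_set(do.call(rbind, c(out, make.row.names = FALSE)),
                  meas$rates, meas$ratios)
}

#' Fractional labeling table for a measurement set
#'
#' @param meas A processed \code{measurement_set} (masses 0..n per fragment).
#' @return data.frame(tracer, fragment, fractional_labeling).
#' @export
fractional_labeling_table <- function(meas) {
  keys <- unique(meas$mdv[, c("tracer", "fragment")])
  keys$fractional_labeling <- vapply(seq_len(nrow(keys)), function(i) {
    g <- meas$mdv[meas$mdv$tracer == keys$tracer[i] &
                    meas$mdv$fragment == keys$fragment[i], ]
    fractional_labeling(g$value[order(g$mass)])
  }, 0)
  keys
}
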