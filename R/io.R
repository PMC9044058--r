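# CSV dialect: UTF-8, '#' comment lines carrying key=value metadata before
# the header, decimal point, no locale handling.

.meta_lines <- function(kv) {
  paste0("# ", names(kv), "=", vapply(kv, format, character(1),
                                      digits = 15))
}

.read_meta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty file: ", path)
  cm <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (l in cm) {
    l <- sub("^#\\s*", "", l)
    eq <- regexpr("=", l, fixed = TRUE)
    if (eq > 0)
      kv[[substr(l, 1, eq - 1)]] <- substr(l, eq + 1, nchar(l))
  }
  n_skip <- length(cm)
  if (n_skip >= length(lines)) stop("no data rows in ", path)
  list(meta = kv, skip = n_skip)
}

#' Write an ITC isotherm to CSV
#'
#' The dialect is plain UTF-8 CSV with `# key=value` comment lines carrying
#' the protocol (cell volume, protein and syringe concentrations,
#' temperature) before the column header.
#'
#' @param isotherm An [`isotherm`][simulate_injection_heats].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_isotherm_csv <- function(isotherm, path) {
  stopifnot(inherits(isotherm, "isotherm"))
  pr <- attr(isotherm, "protocol")
  kv <- c(cell_volume_ul = pr$cell_volume * 1e6,
          p_cell_uM = pr$p_cell * 1e6,
          s_syringe_mM = pr$s_syringe * 1e3,
          temperature_K = pr$temperature)
  if (!is.null(pr$i_cell)) kv <- c(kv, i_cell_uM = pr$i_cell * 1e6)
  cond <- attr(isotherm, "condition")
  if (!is.na(cond)) kv <- c(kv, condition = cond)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.meta_lines(as.list(kv)), con)
  utils::write.csv(as.data.frame(isotherm)[, c(
    "injection_index", "injection_volume_ul", "raw_heat_ucal",
    "normalized_heat_kcal_per_mol", "molar_ratio")],
    con, row.names = FALSE)
  invisible(path)
}

#' Read an ITC isotherm from CSV
#'
#' Counterpart of [write_isotherm_csv()]; rebuilds the titration protocol
#' from the comment metadata and validates the isotherm invariants (strictly
#' increasing molar ratio, consistent normalization).
#'
#' @param path File written by [write_isotherm_csv()].
#' @return An [`isotherm`][simulate_injection_heats].
#' @export
read_isotherm_csv <- function(path) {
  hdr <- .read_meta(path)
  need <- c("cell_volume_ul", "p_cell_uM", "s_syringe_mM", "temperature_K")
  miss <- setdiff(need, names(hdr$meta))
  if (length(miss))
    stop("missing metadata key(s): ", paste(miss, collapse = ", "))
  df <- utils::read.csv(path, comment.char = "#")
  need_cols <- c("injection_index", "injection_volume_ul", "raw_heat_ucal",
                 "normalized_heat_kcal_per_mol", "molar_ratio")
  miss <- setdiff(need_cols, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("no injections in ", path)
  bad <- which(diff(df$molar_ratio) <= 0)
  if (length(bad))
    stop("molar ratio not strictly increasing at data row(s): ",
         paste(bad + 1L, collapse = ", "))
  m <- hdr$meta
  protocol <- titration_protocol(
    p_cell = as.numeric(m$p_cell_uM) * 1e-6,
    s_syringe = as.numeric(m$s_syringe_mM) * 1e-3,
    cell_volume = as.numeric(m$cell_volume_ul) * 1e-6,
    injection_volumes = df$injection_volume_ul * 1e-6,
    temperature = as.numeric(m$temperature_K),
    i_cell = if (!is.null(m$i_cell_uM)) as.numeric(m$i_cell_uM) * 1e-6)
  df$moles_injected <- protocol$s_syringe * df$injection_volume_ul * 1e-6
  df <- df[, c("injection_index", "injection_volume_ul", "moles_injected",
               "molar_ratio", "raw_heat_ucal",
               "normalized_heat_kcal_per_mol")]
  .new_isotherm(df, protocol,
                condition = if (is.null(m$condition)) NA_character_
                else m$condition)
}

#' Write / read uptake trace sets
#'
#' Long-format trace CSV (`trace_id`, `condition`, `time_s`, `efret`,
#' `responding`) plus a video-metadata CSV (`condition`, `n_total`,
#' `n_responding`, `t0_s`).
#'
#' @param x An [uptake_trace_set()].
#' @param traces_path,meta_path File paths.
#' @return `write_uptake_csv`: the paths, invisibly. `read_uptake_csv`: an
#'   [uptake_trace_set()].
#' @export
write_uptake_csv <- function(x, traces_path, meta_path) {
  stopifnot(inherits(x, "uptake_traces"))
  utils::write.csv(x$traces, traces_path, row.names = FALSE)
  utils::write.csv(x$meta, meta_path, row.names = FALSE)
  invisible(c(traces_path, meta_path))
}

#' @rdname write_uptake_csv
#' @export
read_uptake_csv <- function(traces_path, meta_path) {
  for (p in c(traces_path, meta_path)) {
    ln <- readLines(p, warn = FALSE)
    if (length(ln) <= 1L) stop("empty or header-only file: ", p)
  }
  traces <- utils::read.csv(traces_path)
  meta <- utils::read.csv(meta_path)
  uptake_trace_set(traces, meta)
}

#' Protein concentration from A280 absorbance
#'
#' Beer-Lambert conversion with the transporter protomer's experimentally
#' determined extinction coefficient of 57,400 / (M cm):
#' `c = a280 * dilution_factor / (57400 * pathlength)`.
#'
#' @param a280 Absorbance at 280 nm, > 0.
#' @param dilution_factor Fold dilution of the measured sample (e.g. 40 for
#'   a 1:40 dilution), > 0.
#' @param pathlength Cuvette path length in cm (default 1).
#' @param extinction Molar extinction coefficient, 1/(M cm).
#' @return Protomer concentration, molar.
#' @examples
#' protein_concentration_from_a280(0.574)            # 10 uM
#' protein_concentration_from_a280(0.35, dilution_factor = 40)  # 243.9 uM
#' @export
protein_concentration_from_a280 <- function(a280, dilution_factor = 1,
                                            pathlength = 1,
                                            extinction = 57400) {
  stopifnot(is.numeric(a280), is.numeric(dilution_factor),
            is.numeric(pathlength), is.numeric(extinction))
  if (any(a280 <= 0) || any(dilution_factor <= 0) || any(pathlength <= 0) ||
      any(extinction <= 0))
    stop("all inputs must be positive")
  a280 * dilution_factor / (extinction * pathlength)
}
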