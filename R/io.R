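#' Write an EOS table to CSV
#'
#' Plain CSV with commented key-value metadata lines (`# key = value`)
#' carrying temperature (Celsius), salt molarity and valence, followed by a
#' header `rho_per_nm3,betaP_per_nm3[,sigma_betaP]`.
#'
#' @param table An [eos_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_eos_table <- function(table, path) {
  if (!inherits(table, "eos_table")) {
    abort("`table` must be an eos_table.", class = "nanostarphase_usage_error")
  }
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(
    sprintf("# temperature_C = %.10g", kelvin_to_celsius(attr(table, "T_K"))),
    sprintf("# salt_M = %.10g", attr(table, "S")),
    sprintf("# valence = %d", as.integer(attr(table, "f")))
  )
  writeLines(meta, con)
  df <- as.data.frame(table)
  # %.17g guarantees value-exact (bit-identical) numeric round trips
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(do.call(paste, c(lapply(df, function(x) sprintf("%.17g", x)),
                              sep = ",")), con)
  invisible(path)
}

#' Read an EOS table from CSV
#'
#' Inverse of [write_eos_table()]. Metadata lines are optional; malformed
#' numeric fields raise a parse error naming the line.
#'
#' @param path CSV file path.
#' @return An [eos_table()].
#' @export
read_eos_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("EOS table file not found: %s", path),
          class = "nanostarphase_usage_error")
  }
  lines <- readLines(path)
  meta_idx <- grep("^\\s*#", lines)
  meta <- list(T_K = NA_real_, S = NA_real_, f = NA_integer_)
  for (ln in lines[meta_idx]) {
    kv <- sub("^\\s*#\\s*", "", ln)
    parts <- strsplit(kv, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2) next
    key <- trimws(parts[1]); val <- trimws(parts[2])
    if (key == "temperature_C") meta$T_K <- celsius_to_kelvin(as.numeric(val))
    if (key == "salt_M") meta$S <- as.numeric(val)
    if (key == "valence") meta$f <- as.integer(val)
  }
  body <- lines[setdiff(seq_along(lines), meta_idx)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2) {
    abort(sprintf("No data rows in %s.", path),
          class = "nanostarphase_insufficient_data_error")
  }
  df <- tryCatch(
    utils::read.csv(text = body, stringsAsFactors = FALSE),
    error = function(e) abort(sprintf("Failed to parse %s: %s", path,
                                      conditionMessage(e)),
                              class = "nanostarphase_parse_error"))
  needed <- c("rho_per_nm3", "betaP_per_nm3")
  if (!all(needed %in% names(df))) {
    abort(sprintf("%s must have columns %s.", path, paste(needed, collapse = ", ")),
          class = "nanostarphase_parse_error")
  }
  bad <- which(!is.finite(df$rho_per_nm3) | !is.finite(df$betaP_per_nm3))
  if (length(bad)) {
    abort(sprintf("Non-numeric value in %s at data row %d.", path, bad[1]),
          class = "nanostarphase_parse_error")
  }
  eos_table(df$rho_per_nm3, df$betaP_per_nm3,
            sigma_betaP = if ("sigma_betaP" %in% names(df)) df$sigma_betaP,
            T_K = meta$T_K, S = meta$S, f = meta$f)
}

#' Write a binodal to CSV
#'
#' Columns `T_K, T_C, rho_gas_per_nm3, rho_liq_per_nm3, betaP_per_nm3, mu`,
#' preceded by commented metadata including the critical point and, when
#' available, a config hash for provenance.
#'
#' @param binodal A tibble from [coexistence_curve()].
#' @param path Output file path.
#' @param config_hash Optional provenance string embedded in the header.
#' @return `path`, invisibly.
#' @export
write_binodal <- function(binodal, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  cp <- attr(binodal, "critical")
  meta <- character()
  if (!is.null(cp)) {
    meta <- c(meta,
              sprintf("# Tc_K = %.10g", cp$Tc),
              sprintf("# rho_c_per_nm3 = %.10g", cp$rho_c))
  }
  if (!is.null(config_hash)) meta <- c(meta, sprintf("# config_hash = %s", config_hash))
  if (length(meta)) writeLines(meta, con)
  utils::write.csv(as.data.frame(binodal), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run configuration file
#'
#' Plain-text `key = value` configuration with `#` comments. Every physical
#' key carries an explicit unit suffix (`_cal_per_mol`, `_C`, `_M`, `_nm3`,
#' ...) because mixed units are the likeliest user error. Unknown keys raise
#' a usage error naming the key; referenced file paths are checked for
#' existence at load time.
#'
#' @param path Configuration file path.
#' @return A named list of resolved values merged over the packaged defaults.
#' @export
read_run_config <- function(path) {
  defaults <- list(
    delta_H_cal_per_mol = -54000,
    delta_S_nosalt = -151.99,
    L_DNA = 6L,
    v_b_nm3 = 1.6606,
    tail.enabled = FALSE,
    tail.ddH = 0, tail.ddS_a = 0, tail.ddS_b = 0,
    valence = 4L,
    salt_M = 0.5,
    temperature_C = NA_real_,
    reference = "virial2",
    B2_nm3 = NA_real_, B3_nm6 = 0,
    eos_table_path = NA_character_,
    T_min_C = -10, T_max_C = 100,
    n_starts = 12L,
    seed = 1L,
    out_dir = "."
  )
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path),
          class = "nanostarphase_usage_error")
  }
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- defaults
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2) {
      abort(sprintf("Malformed config line: '%s'", ln),
            class = "nanostarphase_usage_error")
    }
    key <- trimws(parts[1]); val <- trimws(parts[2])
    if (!key %in% names(defaults)) {
      abort(sprintf("Unknown config key: '%s'", key),
            class = "nanostarphase_usage_error")
    }
    proto <- defaults[[key]]
    cfg[[key]] <- if (is.logical(proto)) {
      tolower(val) %in% c("true", "yes", "on", "1")
    } else if (is.integer(proto)) {
      as.integer(val)
    } else if (is.numeric(proto)) {
      as.numeric(val)
    } else val
  }
  if (!is.na(cfg$eos_table_path) && !file.exists(cfg$eos_table_path)) {
    abort(sprintf("Referenced EOS table does not exist: %s", cfg$eos_table_path),
          class = "nanostarphase_usage_error")
  }
  cfg
}

#' Build a free-energy model from a run configuration
#'
#' @param cfg A list from [read_run_config()].
#' @return An `fe_model`.
#' @export
model_from_config <- function(cfg) {
  params <- sticky_end_params(cfg$delta_H_cal_per_mol, cfg$delta_S_nosalt,
                              cfg$L_DNA, cfg$v_b_nm3)
  tail <- tail_correction(cfg$tail.enabled, cfg$tail.ddH, cfg$tail.ddS_a, cfg$tail.ddS_b)
  B2 <- cfg$B2_nm3
  B3 <- cfg$B3_nm6
  if (is.na(B2)) {
    dft <- synthetic_virial_defaults(cfg$salt_M)
    B2 <- dft$B2
    if (cfg$reference == "virial3" && (is.null(B3) || B3 == 0)) B3 <- dft$B3
  }
  table <- if (cfg$reference == "ti") read_eos_table(cfg$eos_table_path)
  free_energy_model(cfg$reference, B2 = B2, B3 = B3, table = table,
                    params = params, salt = cfg$salt_M, tail = tail,
                    valence = cfg$valence,
                    T_range = celsius_to_kelvin(c(cfg$T_min_C, cfg$T_max_C)))
}

config_hash <- function(cfg) {
  txt <- paste(names(cfg), vapply(cfg, function(x) paste(format(x), collapse = ","),
                                  character(1)),
               sep = "=", collapse = ";")
  # small stable polynomial hash; provenance marker, not cryptographic
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
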