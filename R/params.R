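#' Read a flat parameter file
#'
#' Parameter files are plain text with three whitespace-separated columns:
#' name, value, unit. Lines starting with `#` are comments. The returned
#' vector carries the units and the source path as attributes so that runs
#' can record parameter provenance.
#'
#' @param path file path
#' @param required character vector of names that must be present (schema)
#' @return named numeric vector with `units` and `source` attributes
#' @export
read_param_file <- function(path, required = NULL) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(sub("#.*$", "", ln))
  ln <- ln[nzchar(ln)]
  parts <- strsplit(ln, "[[:space:]]+")
  bad <- vapply(parts, function(p) length(p) < 2L, logical(1))
  if (any(bad)) stop("malformed parameter line(s): ", paste(ln[bad], collapse = "; "))
  nm <- vapply(parts, `[[`, "", 1L)
  val <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(val)) stop("non-numeric value for: ", paste(nm[is.na(val)], collapse = ", "))
  if (anyDuplicated(nm)) stop("duplicate parameter name(s): ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  un <- vapply(parts, function(p) if (length(p) >= 3L) p[[3L]] else "", "")
  x <- stats::setNames(val, nm)
  if (!is.null(required)) {
    miss <- setdiff(required, nm)
    if (length(miss)) stop("parameter file ", path, " is missing: ",
                           paste(miss, collapse = ", "))
    extra <- setdiff(nm, required)
    if (length(extra)) stop("unknown parameter(s) in ", path, ": ",
                            paste(extra, collapse = ", "))
  }
  attr(x, "units") <- stats::setNames(un, nm)
  attr(x, "source") <- path
  x
}

.tp06_param_names <- c(
  "R_gas", "T_temp", "F_faraday", "Cm", "V_c", "V_sr", "V_ss",
  "K_o", "Na_o", "Ca_o",
  "G_Na", "G_K1", "G_to", "G_Kr", "G_Ks", "G_CaL", "G_bNa", "G_bCa",
  "G_pCa", "K_pCa", "G_pK", "p_KNa",
  "P_NaK", "K_mK", "K_mNa",
  "k_NaCa", "K_mNai", "K_mCa", "k_sat", "gamma_NaCa", "alpha_NaCa",
  "Vmax_up", "K_up", "V_rel", "k1_prime", "k2_prime", "k3", "k4",
  "EC", "max_sr", "min_sr", "V_leak", "V_xfer",
  "Buf_c", "K_bufc", "Buf_sr", "K_bufsr", "Buf_ss", "K_bufss")

.nhs_param_names <- c(
  "k_on", "k_ref_off", "gamma_trpn", "ca_trpn_max",
  "alpha_0", "alpha_r1", "alpha_r2", "n_rel", "K_z", "n_hill",
  "ca_50ref", "z_p", "beta_0", "beta_1", "T_ref", "a_xb",
  "A1", "A2", "A3", "alpha_1", "alpha_2", "alpha_3",
  "lambda_lo", "lambda_hi", "k_off_min_frac", "dlam_tau")
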