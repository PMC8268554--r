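#' Built-in tissue property table
#'
#' Electrical and thermal properties for the tissues of the synthetic torso
#' phantom. Electrical conductivities are given at a low (kHz-range, `sigma_lf`)
#' and a high (MHz-range, `sigma_hf`) measurement frequency. The values are a
#' compact approximation of typical literature/database values spanning the
#' conductivity range found in the human torso (from internal air near 0 S/m,
#' through muscle at 0.36 S/m, up to urine at 3 S/m); they are not a certified
#' property database and can be overridden by passing a modified table to the
#' phantom builder.
#'
#' Columns:
#' \describe{
#'   \item{name}{tissue label}
#'   \item{sigma_lf, sigma_hf}{electrical conductivity at the two frequencies
#'     (S/m)}
#'   \item{tc}{temperature coefficient of conductivity (fraction per degree C;
#'     0.02 = 2 %/degree C for all tissues)}
#'   \item{alpha_lf, alpha_hf}{effective plasma volume fraction seen by the
#'     current at each frequency (dimensionless; defaults 0.24 and 0.08)}
#'   \item{rho}{density (kg/m^3)}
#'   \item{c}{specific heat capacity (J/(kg C))}
#'   \item{k}{thermal conductivity (W/(m C))}
#'   \item{wb0}{baseline blood perfusion (kg/(s m^3))}
#'   \item{qm}{metabolic heat generation (W/m^3); assumed balanced at 37 C}
#'   \item{perfusion_responsive}{logical; whether heating raises perfusion in
#'     this tissue (muscle, fat and tumor)}
#' }
#'
#' @param tc temperature coefficient applied to all tissues (fraction per C).
#' @param alpha_lf,alpha_hf plasma volume fractions applied to all tissues.
#' @return a `data.frame`, one row per tissue; row order defines the integer
#'   tissue ids used in mesh labels.
#' @export
#' @examples
#' tissue_table()
tissue_table <- function(tc = 0.02, alpha_lf = 0.24, alpha_hf = 0.08) {
  stopifnot(tc >= 0, alpha_lf >= 0, alpha_lf < 1, alpha_hf >= 0, alpha_hf < 1)
  tab <- data.frame(
    name     = c("muscle", "fat", "skin", "bone", "organ", "urine", "tumor", "air"),
    sigma_lf = c(0.36,     0.04,  0.10,   0.02,   0.08,    3.00,    0.30,    0.0),
    sigma_hf = c(0.50,     0.06,  0.25,   0.04,   0.15,    3.00,    0.45,    0.0),
    rho      = c(1090,     911,   1109,   1908,   1079,    1000,    1050,    1.2),
    c        = c(3421,     2348,  3391,   1313,   3540,    4180,    3800,    1000),
    k        = c(0.49,     0.21,  0.37,   0.32,   0.52,    0.60,    0.51,    0.026),
    wb0      = c(0.70,     0.30,  1.80,   0.06,   5.00,    0.00,    0.80,    0.00),
    qm       = c(990,      300,   1600,   70,     9000,    0,       5000,    0),
    perfusion_responsive = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  tab$tc <- tc
  tab$alpha_lf <- alpha_lf
  tab$alpha_hf <- alpha_hf
  rownames(tab) <- tab$name
  tab
}

#' Map tissue names to integer ids
#'
#' @param names character vector of tissue names.
#' @param table tissue table (see [tissue_table()]).
#' @return integer row indices into `table`.
#' @export
tissue_id <- function(names, table = tissue_table()) {
  id <- match(names, table$name)
  if (anyNA(id)) stop("unknown tissue: ", paste(names[is.na(id)], collapse = ", "))
  id
}

#' Per-element conductivity from tissue labels
#'
#' @param labels integer tissue ids per element.
#' @param table tissue table.
#' @param frequency `"lf"` or `"hf"`.
#' @return numeric vector of conductivities (S/m).
#' @export
sigma_from_labels <- function(labels, table = tissue_table(),
                              frequency = c("lf", "hf")) {
  frequency <- match.arg(frequency)
  col <- if (frequency == "lf") "sigma_lf" else "sigma_hf"
  stopifnot(all(labels >= 1L), all(labels <= nrow(table)))
  table[[col]][labels]
}
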