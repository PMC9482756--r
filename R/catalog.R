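#' Convert inches to metres
#'
#' Archwire cross-sections are specified clinically in inches; all internal
#' computation is in SI. The conversion is exact: 1 in = 0.0254 m.
#'
#' @param x Length(s) in inches (`in_to_m`) or metres (`m_to_in`).
#' @return Numeric vector of converted lengths.
#' @export
#' @examples
#' in_to_m(0.016)
in_to_m <- function(x) x * 0.0254

#' @rdname in_to_m
#' @export
m_to_in <- function(x) x / 0.0254

#' Second moment of area of a round wire cross-section
#'
#' For a round wire of diameter `D`, the second moment of area about the
#' bending axis is \eqn{I_z = \pi D^4 / 64}.
#'
#' @param D Diameter in metres. Must be positive.
#' @return Second moment of area in m^4.
#' @export
#' @examples
#' second_moment_round(in_to_m(0.014))
second_moment_round <- function(D) {
  if (!is.numeric(D) || any(!is.finite(D)) || any(D <= 0)) {
    rlang::abort("`D` must be a positive finite diameter in metres.",
                 class = "tloop_input_error")
  }
  pi * D^4 / 64
}

#' Second moment of area of a rectangular wire cross-section
#'
#' For a rectangular wire, \eqn{I_z = c_1 c_2^3 / 12}, where `c2` is the side
#' lying in the bending plane (it enters cubed) and `c1` the side
#' perpendicular to the bending axis (it enters linearly).
#'
#' @param c1 Side length entering linearly, metres. Must be positive.
#' @param c2 Side length entering cubed, metres. Must be positive.
#' @return Second moment of area in m^4.
#' @export
#' @examples
#' second_moment_rect(in_to_m(0.022), in_to_m(0.016))
second_moment_rect <- function(c1, c2) {
  if (!is.numeric(c1) || !is.numeric(c2) ||
      any(!is.finite(c1)) || any(!is.finite(c2)) ||
      any(c1 <= 0) || any(c2 <= 0)) {
    rlang::abort("`c1` and `c2` must be positive finite side lengths in metres.",
                 class = "tloop_input_error")
  }
  c1 * c2^3 / 12
}

#' Material constants used in the analysis
#'
#' Returns the packaged material table: archwire alloys (stainless steel,
#' Australian) together with the oral-tissue and bracket entries carried for
#' completeness. Values are stored exactly as published for the reference
#' study this package reproduces.
#'
#' @return A tibble with columns `name`, `E_GPa`, `nu`, `sigma_e_GPa`,
#'   `sigma_b_GPa`, `density_mg_cm3`.
#' @export
wire_materials <- function() {
  path <- system.file("extdata", "materials.csv", package = "tloop",
                      mustWork = TRUE)
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  bad <- out$E_GPa <= 0 | out$nu < 0 | out$nu >= 0.5
  if (any(bad)) {
    rlang::abort("materials table violates its invariants (E > 0, 0 <= nu < 0.5).",
                 class = "tloop_data_integrity_error")
  }
  out
}

# roman codenames in catalogue order
.tloop_codenames <- c("I", "II", "III", "IV", "V", "VI", "VII",
                      "VIII", "IX", "X", "XI")

#' Catalogue of the eleven clinical archwires
#'
#' The eleven archwires are codenamed I--XI: I--III are rectangular stainless
#' steel (0.016 x 0.016, 0.016 x 0.022, 0.016 x 0.025 in), IV--VII round
#' stainless steel and VIII--XI round Australian wire (0.014--0.020 in
#' diameters). Inch dimensions are converted at exactly 1 in = 0.0254 m and
#' the second moment of area `I_z_m4` is computed from the shape formula.
#'
#' For the rectangular wires the varying dimension (0.016/0.022/0.025 in) is
#' the linearly entering side `c1`; the fixed 0.016 in side lies in the
#' bending plane (`c2`, cubed). This orientation is the one consistent with
#' the reference dataset: displacement ratios across I--III scale linearly,
#' not cubically, in the varying side.
#'
#' @return A tibble with one row per codename: `codename`, `alias`,
#'   `material`, `shape`, `dim1_in`, `dim2_in`, `E_Pa`, `nu`, `sigma_e_Pa`,
#'   `sigma_b_Pa`, `D_m`, `c1_m`, `c2_m`, `I_z_m4`.
#' @export
#' @examples
#' archwire_catalog()
archwire_catalog <- function() {
  path <- system.file("extdata", "archwires.csv", package = "tloop",
                      mustWork = TRUE)
  wires <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  mats <- wire_materials()
  out <- wires |>
    dplyr::left_join(mats, by = c(material = "name")) |>
    dplyr::mutate(
      E_Pa = .data$E_GPa * 1e9,
      sigma_e_Pa = .data$sigma_e_GPa * 1e9,
      sigma_b_Pa = .data$sigma_b_GPa * 1e9,
      D_m  = ifelse(.data$shape == "round", in_to_m(.data$dim1_in), NA_real_),
      c1_m = ifelse(.data$shape == "rectangular", in_to_m(.data$dim1_in), NA_real_),
      c2_m = ifelse(.data$shape == "rectangular", in_to_m(.data$dim2_in), NA_real_),
      I_z_m4 = ifelse(.data$shape == "round",
                      pi * .data$D_m^4 / 64,
                      .data$c1_m * .data$c2_m^3 / 12)
    ) |>
    dplyr::select("codename", "alias", "material", "shape", "dim1_in",
                  "dim2_in", "E_Pa", "nu", "sigma_e_Pa", "sigma_b_Pa",
                  "D_m", "c1_m", "c2_m", "I_z_m4")
  stopifnot(identical(out$codename, .tloop_codenames))
  out
}

#' Look up one archwire by codename
#'
#' Accepts the roman codename (`"IV"`) or the material/size alias
#' (`"S0014"`, `"A0016"`), case-insensitively.
#'
#' @param codename Character scalar identifying the wire.
#' @return A one-row tibble as in [archwire_catalog()].
#' @export
#' @examples
#' lookup_archwire("IV")
#' lookup_archwire("s1622")
lookup_archwire <- function(codename) {
  if (!is.character(codename) || length(codename) != 1L || is.na(codename)) {
    rlang::abort("`codename` must be a single character string.",
                 class = "tloop_input_error")
  }
  cat_tbl <- archwire_catalog()
  key <- toupper(trimws(codename))
  hit <- which(toupper(cat_tbl$codename) == key | toupper(cat_tbl$alias) == key)
  if (length(hit) != 1L) {
    rlang::abort(
      paste0("Unknown archwire codename '", codename, "'. Valid names: ",
             paste(cat_tbl$codename, collapse = ", "), " (aliases ",
             paste(cat_tbl$alias, collapse = ", "), ")."),
      class = "tloop_lookup_error")
  }
  cat_tbl[hit, ]
}

# bending stiffness E*I_z of an archwire row (or any list with E_Pa, I_z_m4)
wire_EI <- function(wire) {
  if (is.data.frame(wire)) {
    stopifnot(nrow(wire) == 1L)
    wire <- as.list(wire)
  }
  EI <- wire$E_Pa * wire$I_z_m4
  if (!is.numeric(EI) || !is.finite(EI) || EI <= 0) {
    rlang::abort("wire must carry positive `E_Pa` and `I_z_m4`.",
                 class = "tloop_input_error")
  }
  EI
}

#' T-loop geometry
#'
#' Bundles the loop dimensions: bend radius of the arc portion `R`, total
#' loop height `h`, vertical-arm length `y` and total horizontal-arm length
#' of the arc section `w`. `h` is recorded and validated but enters none of
#' the closed forms. Arguments are in millimetres (the clinical unit); the
#' stored values are metres.
#'
#' Defaults describe a typical clinical closing T-loop: R = 1 mm, y = 7 mm,
#' w = 5 mm, h = 8 mm.
#'
#' @param R_mm Arc bend radius, mm (> 0).
#' @param y_mm Vertical-arm length, mm (> R).
#' @param w_mm Total arc horizontal-arm length, mm (> R).
#' @param h_mm Total loop height, mm; a warning is issued when h < y.
#' @return An object of class `tloop_geometry`: a list with elements
#'   `R`, `y`, `w`, `h` in metres.
#' @export
#' @examples
#' tloop_geometry(R_mm = 1, y_mm = 8, w_mm = 6, h_mm = 10)
tloop_geometry <- function(R_mm = 1, y_mm = 7, w_mm = 5, h_mm = 8) {
  vals <- c(R_mm = R_mm, y_mm = y_mm, w_mm = w_mm, h_mm = h_mm)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    rlang::abort("All geometry dimensions must be positive and finite.",
                 class = "tloop_input_error")
  }
  if (y_mm <= R_mm) {
    rlang::abort("Vertical-arm length y must exceed the bend radius R.",
                 class = "tloop_input_error")
  }
  if (w_mm <= R_mm) {
    rlang::abort("Horizontal-arm length w must exceed the bend radius R.",
                 class = "tloop_input_error")
  }
  if (h_mm < y_mm) {
    rlang::warn("Loop height h is smaller than the vertical-arm length y.")
  }
  structure(list(R = R_mm * 1e-3, y = y_mm * 1e-3,
                 w = w_mm * 1e-3, h = h_mm * 1e-3),
            class = "tloop_geometry")
}

#' @export
print.tloop_geometry <- function(x, ...) {
  cat(sprintf("T-loop geometry: R = %.3g mm, y = %.3g mm, w = %.3g mm, h = %.3g mm\n",
              x$R * 1e3, x$y * 1e3, x$w * 1e3, x$h * 1e3))
  invisible(x)
}
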