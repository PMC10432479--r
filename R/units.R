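# Unit-suffixed quantities.  Configs carry explicit unit strings; everything
# internal is SI (m, m^2, m^-2, m^3/s, Pa.s, T, A/m).

.unit_table <- list(
  # length -> m
  "nm"    = c(1e-9,  "length"),
  "um"    = c(1e-6,  "length"),
  "mm"    = c(1e-3,  "length"),
  "cm"    = c(1e-2,  "length"),
  "m"     = c(1,     "length"),
  # area -> m^2
  "nm^2"  = c(1e-18, "area"),
  "um^2"  = c(1e-12, "area"),
  "mm^2"  = c(1e-6,  "area"),
  "cm^2"  = c(1e-4,  "area"),
  "m^2"   = c(1,     "area"),
  # areal density -> m^-2
  "nm^-2" = c(1e18,  "areal_density"),
  "um^-2" = c(1e12,  "areal_density"),
  "cm^-2" = c(1e4,   "areal_density"),
  "m^-2"  = c(1,     "areal_density"),
  # volumetric flow -> m^3/s
  "mL/h"   = c(1e-6 / 3600,  "flow"),
  "mL/hr"  = c(1e-6 / 3600,  "flow"),
  "mL/min" = c(1e-6 / 60,    "flow"),
  "uL/min" = c(1e-9 / 60,    "flow"),
  "L/h"    = c(1e-3 / 3600,  "flow"),
  "m^3/s"  = c(1,            "flow"),
  # dynamic viscosity -> Pa s
  "Pa.s"  = c(1,    "viscosity"),
  "Pa*s"  = c(1,    "viscosity"),
  "mPa.s" = c(1e-3, "viscosity"),
  # magnetic flux density -> T
  "T"     = c(1,    "flux_density"),
  "mT"    = c(1e-3, "flux_density"),
  "G"     = c(1e-4, "flux_density"),
  "Gauss" = c(1e-4, "flux_density"),
  # magnetic field strength / magnetization -> A/m
  "A/m"   = c(1,   "field_strength"),
  "kA/m"  = c(1e3, "field_strength"),
  # mass magnetization -> A m^2 / kg
  "Am^2/kg" = c(1, "mass_magnetization"),
  # times
  "s"     = c(1,    "time"),
  "min"   = c(60,   "time"),
  "h"     = c(3600, "time"),
  # speed
  "m/s"   = c(1,    "speed"),
  "um/s"  = c(1e-6, "speed")
)
# bare numbers (dimensionless)
.unit_table <- c(.unit_table, stats::setNames(list(c(1, "dimensionless")), ""))

#' Parse a quantity string with an explicit unit into SI
#'
#' Accepts either a bare numeric (assumed SI) or a string such as
#' `"2.5 mL/h"`, `"200 nm"`, `"2.12e6 cm^-2"`, `"0.4 T"`.  The micro sign is
#' accepted as a synonym for `u`.
#'
#' @param x numeric (returned unchanged) or a single string `"<number> <unit>"`.
#' @param dimension optional dimension name (`"length"`, `"area"`,
#'   `"areal_density"`, `"flow"`, `"viscosity"`, `"flux_density"`,
#'   `"field_strength"`, ...).  If given, the unit must carry that dimension.
#' @return numeric value in SI units.
#' @examples
#' parse_quantity("2.5 mL/h")   # 6.944e-10 m^3/s
#' parse_quantity("200 nm")     # 2e-07 m
#' @export
parse_quantity <- function(x, dimension = NULL) {
  if (is.numeric(x)) {
    return(as.numeric(x))
  }
  if (!is.character(x) || length(x) != 1L) {
    stop("quantity must be a numeric or a single \"<number> <unit>\" string")
  }
  s <- gsub("µ|μ", "u", trimws(x))
  m <- regmatches(s, regexec("^([-+]?[0-9.]+(?:[eE][-+]?[0-9]+)?)\\s*(.*)$", s))[[1]]
  if (length(m) != 3L) {
    stop(sprintf("cannot parse quantity '%s'", x))
  }
  val <- as.numeric(m[2])
  unit <- trimws(m[3])
  entry <- .unit_table[[unit]]
  if (is.null(entry)) {
    stop(sprintf("unknown unit '%s' in quantity '%s'", unit, x))
  }
  if (!is.null(dimension) && entry[2] != dimension) {
    stop(sprintf("quantity '%s' has dimension '%s', expected '%s'",
                 x, entry[2], dimension))
  }
  val * as.numeric(entry[1])
}

# vacuum permeability [T m / A]
MU0 <- 4e-7 * pi
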