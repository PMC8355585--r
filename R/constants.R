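#' @keywords internal
"_PACKAGE"

## Single source of truth for atomic constants.
## Monoisotopic masses (Da) of principal isotopes; D and O18 are the exact
## masses of 2H and 18O, used as fixed-mass pseudo-elements for isotope labels.
ATOMIC_MASS <- c(
  C   = 12.0,
  H   = 1.00782503207,
  N   = 14.0030740048,
  O   = 15.9949146196,
  F   = 18.99840322,
  Na  = 22.9897692809,
  K   = 38.96370668,
  D   = 2.01410177785,
  O18 = 17.9991610
)

ELECTRON_MASS <- 0.00054857990907

## 13C - 12C mass difference: nominal spacing of unit-mass isotopologue bins.
ISOTOPE_SPACING <- 1.0033548378

MASS_H2O <- 2 * ATOMIC_MASS[["H"]] + ATOMIC_MASS[["O"]]
MASS_PROTON <- ATOMIC_MASS[["H"]] - ELECTRON_MASS

## Natural isotope abundances by nominal mass offset from the principal
## isotope (offset 0). Label pseudo-elements D and O18 are treated as
## isotopically pure. Values: CIAAW representative abundances.
ISOTOPE_ABUNDANCE <- list(
  C   = c(0.9893, 0.0107),
  H   = c(0.999885, 0.000115),
  N   = c(0.99636, 0.00364),
  O   = c(0.99757, 0.00038, 0.00205),
  F   = 1,
  Na  = 1,
  K   = c(0.932581, 0.000117, 0.067302),
  D   = 1,
  O18 = 1
)

SUPPORTED_ELEMENTS <- names(ATOMIC_MASS)

## Dehydro (residue) formulas of the monosaccharide classes.
RESIDUE_FORMULA <- list(
  hex    = c(C = 6, H = 10, O = 5),
  hexnac = c(C = 8, H = 13, N = 1, O = 5),
  dhex   = c(C = 6, H = 10, O = 4),
  neuac  = c(C = 11, H = 17, N = 1, O = 8),
  neugc  = c(C = 11, H = 17, N = 1, O = 9)
)

MONO_NAMES <- c(hex = "Hex", hexnac = "HexNAc", dhex = "dHex",
                neuac = "NeuAc", neugc = "NeuGc")
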