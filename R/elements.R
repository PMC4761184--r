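# Element tables shared by the parser, validator and canonicalizer.
# Codes are fixed package-wide so that canonical labelings are comparable
# across molecules.

.UB_ELEMENTS <- c(
  "C", "N", "O", "P", "S", "Si", "H", "B", "F", "Cl", "Br", "I", "Se",
  "Li", "Na", "K", "Rb", "Cs", "Mg", "Ca", "Sr", "Ba", "Al", "Ga", "Ge",
  "As", "Sb", "Bi", "Sn", "Pb", "Tl", "Zn", "Cd", "Hg", "Cu", "Ag", "Au",
  "Ni", "Pd", "Pt", "Co", "Fe", "Mn", "Cr", "Mo", "W", "V", "Ti", "Te"
)

# Allowed valence states. C:4, Si:4, N:3, O:2, P:{3,5}, S:{2,4,6};
# halogens and alkali metals are monovalent. Elements absent from this
# list (heavy metals etc., seen only in toxicity input that the filters
# reject) are not valence-checked.
.UB_VALENCES <- list(
  C = 4L, Si = 4L, N = 3L, O = 2L, P = c(3L, 5L), S = c(2L, 4L, 6L),
  H = 1L, B = 3L, F = 1L, Cl = 1L, Br = 1L, I = 1L, Se = c(2L, 4L, 6L),
  Li = 1L, Na = 1L, K = 1L, Rb = 1L, Cs = 1L
)

# Elements counted as non-metals when detecting organometallic compounds.
.UB_NONMETALS <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl",
                   "Se", "Br", "I")

.UB_ALKALI <- c("Li", "Na", "K", "Rb", "Cs")
.UB_HALOGENS <- c("F", "Cl", "Br", "I")

# Organic-subset symbols that may be written without brackets in SMILES.
.UB_ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

.elem_code <- function(symbol) {
  code <- match(symbol, .UB_ELEMENTS)
  if (anyNA(code)) {
    bad <- unique(symbol[is.na(code)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  code
}

.elem_valences <- function(symbol) .UB_VALENCES[[symbol]]

.elem_max_valence <- function(symbol) {
  v <- .UB_VALENCES[[symbol]]
  if (is.null(v)) 8L else max(v)
}

# Hydrogens needed to fill an atom to its smallest allowed valence.
# Unknown-valence elements get no implicit hydrogens.
.implicit_h <- function(symbol, bond_sum) {
  v <- .UB_VALENCES[[symbol]]
  if (is.null(v)) return(0L)
  ok <- v[v >= bond_sum]
  if (length(ok) == 0L) return(NA_integer_)
  min(ok) - bond_sum
}
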