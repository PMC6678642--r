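# Small hand-built molecules used across the suite (coordinates in Angstrom).

mol_propane <- function() {
  molecule("propane", c("C", "C", "C"),
           rbind(c(0, 0, 0), c(1.54, 0, 0), c(2.31, 1.33, 0)),
           data.frame(i = c(1, 2), j = c(2, 3), order = c(1, 1)))
}

mol_cyclopropane <- function() {
  r <- 1.51 / sqrt(3)
  ang <- 2 * pi * (0:2) / 3
  molecule("cyclopropane", rep("C", 3),
           cbind(r * cos(ang), r * sin(ang), 0),
           data.frame(i = c(1, 2, 3), j = c(2, 3, 1), order = 1))
}

mol_benzene <- function(kekule = TRUE) {
  ang <- 2 * pi * (0:5) / 6
  molecule("benzene", rep("C", 6),
           cbind(1.39 * cos(ang), 1.39 * sin(ang), 0),
           data.frame(i = 1:6, j = c(2:6, 1),
                      order = if (kekule) rep(c(2, 1), 3) else rep(4, 6)))
}

mol_methane <- function() {
  d <- 1.09 / sqrt(3)
  molecule("methane", c("C", "H", "H", "H", "H"),
           rbind(c(0, 0, 0), c(d, d, d), c(d, -d, -d), c(-d, d, -d),
                 c(-d, -d, d)),
           data.frame(i = 1, j = 2:5, order = 1))
}

mol_ethane <- function() {
  molecule("ethane", c("C", "C"), rbind(c(0, 0, 0), c(1.54, 0, 0)),
           data.frame(i = 1, j = 2, order = 1))
}

mol_helium <- function() {
  molecule("helium", "He", rbind(c(0, 0, 0)))
}

# a deterministic stub conformer provider: chain geometry from the SMILES
# length, no chemistry -- exercises the reader path without OpenBabel
stub_conformer_provider <- function() {
  function(smiles, id, date = NULL) {
    if (grepl("XX", smiles)) return(NULL)           # simulated parse failure
    els <- regmatches(smiles, gregexpr("Cl|Br|[CNOSFP]", smiles))[[1]]
    if (!length(els)) return(NULL)
    n <- length(els)
    coords <- cbind(1.5 * (seq_len(n) - 1), 0, 0)
    bonds <- if (n > 1) data.frame(i = seq_len(n - 1), j = 2:n, order = 1)
             else empty_bonds()
    molecule(id, els, coords, bonds, smiles = smiles, date = date)
  }
}

# random small fixture molecules, memoized per seed
fixture_mols <- local({
  cache <- new.env(parent = emptyenv())
  function(n = 6, seed = 42, ...) {
    key <- paste(c(n, seed, unlist(list(...))), collapse = "_")
    if (is.null(cache[[key]]))
      cache[[key]] <- gen_molecules(fixture_spec(n, seed = seed, ...))
    cache[[key]]
  }
})
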