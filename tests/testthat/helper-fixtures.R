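# shared fixture strings used across test files

# structurally complete worked example: species authorship plus recombined
# infraspecies with basionym and combination authors
carex <- "Carex scirpoidea Michx. subsp. convoluta (Kük.) D.A. Dunlop"

# complex name-strings a regex-based parser cannot decompose
complex_names <- c(
  "Erigeron peregrinus ssp.callianthemus var. eucallianthemus",
  "Polyporus varius var. nummularius f. undulatus (Pilát) Domanski, Orlos & Skirg.",
  "Salvelinus fontinalis x Salmo gairdneri",
  "Echinocereus fasciculatus var. bonkerae × E. fasciculatus var. fasciculatus"
)

# lowercase-initial strings that must never be accepted as scientific names
lowercase_non_names <- c(
  "acid mine drainage metagenome",
  "agricultural soil bacterium CRS5639T18-1",
  "agricultural soil bacterium SC-I-8",
  "algal symbiont of Cladonia variegata MN075",
  "alpha proteobacterium AP-24",
  "anaerobic bacterium ANA No.5",
  "anoxygenic photosynthetic bacterium G16",
  "archaeon enrichment culture clone AOM-SR-A23",
  "bacterium endosymbiont of Plateumaris fulvipes",
  "bacterium enrichment culture DGGE band 61_3_FG_L",
  "barley rhizosphere bacterium JJ-220",
  "bovine rumen bacterium niuO17"
)

warning_codes <- function(row_or_result) {
  w <- if (is.data.frame(row_or_result)) row_or_result$warnings[[1]]
       else row_or_result$warnings
  vapply(w, `[[`, character(1), "code")
}
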