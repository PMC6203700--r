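# Builtin neonatal rabbit brain taxonomy: 89 regions in a hierarchical
# nomenclature. Symmetric structures follow the left/right odd/even id
# convention; midline structures carry a single id with side "median"
# (note 77 and 78 are an odd/even pair of DISTINCT median structures, and
# 218 is a lone even id — which is why pairing is stored explicitly
# rather than derived from parity).

# level, name, abbrev, ids (1 id = median, 2 ids = left,right)
.neonatal_rabbit_rows <- list(
  list("1.1", "Frontal Area",                 "FrA",  c(7L, 8L)),
  list("1.1", "Medial Prefrontal",            "PFrA", c(5L, 6L)),
  list("1.1", "Occipital Area",               "OA",   c(9L, 10L)),
  list("1.1", "Parietal Area",                "PtA",  c(11L, 12L)),
  list("1.1", "Temporal",                     "TeA",  c(13L, 14L)),
  list("1.1", "Cingulate",                    "Cg",   c(15L, 16L)),
  list("1.1", "Retrosplenium",                "RS",   c(17L, 18L)),
  list("1.1", "Insular",                      "Ins",  c(19L, 20L)),
  list("1.2", "Olfactory lobe",               "OB",   c(25L, 26L)),
  list("1.2", "Piriform",                     "Pir",  c(27L, 28L)),
  list("1.3", "Hippocampus",                  "HA",   c(31L, 32L)),
  list("1.3", "Subiculum",                    "S",    c(43L, 44L)),
  list("1.3", "Entorhinal",                   "Ent",  c(45L, 46L)),
  list("1.4", "Claustrum",                    "CL",   c(53L, 54L)),
  list("1.4", "Amygdala",                     "Am",   c(55L, 56L)),
  list("1.5", "Caudate nucleus",              "CN",   c(69L, 70L)),
  list("1.5", "Putamen",                      "Pu",   c(71L, 72L)),
  list("1.5", "Globus Pallidus",              "GP",   c(75L, 76L)),
  list("1.5", "Basal forebrain",              "BF",   77L),
  list("1.5", "Septum",                       "SA",   78L),
  list("2.1", "Thalamus",                     "THA",  c(83L, 84L)),
  list("2.1", "Hypothalamus",                 "HYP",  c(109L, 110L)),
  list("2.1", "Mammillary body",              "MAM",  121L),
  list("2.2", "Midbrain",                     "MB",   127L),
  list("2.2", "Pretectal",                    "PRT",  c(129L, 130L)),
  list("2.2", "Superior colliculus",          "SC",   c(133L, 134L)),
  list("2.2", "Inferior colliculus",          "IC",   c(135L, 136L)),
  list("2.2", "Substantia nigra",             "SN",   c(139L, 140L)),
  list("2.2", "Periaqueductal gray",          "PAG",  c(141L, 142L)),
  list("2.3", "Pons",                         "PO",   151L),
  list("2.3", "Medulla oblongata",            "MY",   153L),
  list("3.1", "Cerebellar vermis",            "VERM", 161L),
  list("3.2", "Cerebellar hemisphere",        "HEM",  c(179L, 180L)),
  list("4",   "Ventricular system",           "VS",   201L),
  list("4",   "Lateral ventricles",           "LV",   c(203L, 204L)),
  list("4",   "Periventricular area",         "PV",   c(211L, 212L)),
  list("5.1", "Optic tract and optic chiasm", "OT",   215L),
  list("5.2", "Corpus callosum",              "cc",   218L),
  list("5.2", "External capsule",             "ec",   c(219L, 220L)),
  list("5.2", "Internal capsule",             "int",  c(223L, 224L)),
  list("5.2", "Corona radiata",               "cr",   c(225L, 226L)),
  list("5.2", "Cerebral peduncle",            "cp",   c(227L, 228L)),
  list("5.2", "Subcortical white matter",     "swm",  c(229L, 230L)),
  list("5.3", "Anterior commissure",          "ac",   233L),
  list("5.3", "Hippocampal commissure",       "hc",   237L),
  list("5.3", "Fimbria of hippocampus",       "fi",   c(239L, 240L)),
  list("5.3", "Columns of the fornix",        "fx",   c(241L, 242L)),
  list("5.3", "Stria terminalis",             "st",   c(243L, 244L)),
  list("5.4", "Mammilothalamic tract",        "mt",   c(247L, 248L)),
  list("5.4", "Fasciculus retroflexus",       "fr",   c(251L, 252L)),
  list("5.4", "Posterior commissure",         "pc",   253L))

build_neonatal_rabbit_taxonomy <- function() {
  rows <- lapply(.neonatal_rabbit_rows, function(r) {
    level <- r[[1]]; name <- r[[2]]; abbrev <- r[[3]]; ids <- r[[4]]
    if (length(ids) == 1L) {
      data.frame(id = ids, name = name, abbrev = abbrev,
                 side = "median", pair_id = NA_integer_, level = level,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(
        id = ids,
        name = paste(name, c("left", "right")),
        abbrev = paste0(abbrev, c("_L", "_R")),
        side = c("left", "right"),
        pair_id = rev(ids),
        level = level,
        stringsAsFactors = FALSE)
    }
  })
  taxonomy(do.call(rbind, rows), name = "neonatal_rabbit")
}

# Default grouping of the 89 regions into 16 macro-regions, used for
# validation-scale reporting.
.default_macro_rows <- list(
  list(1L,  "Corticospinal Tract",     c(223L, 224L, 225L, 226L, 227L, 228L, 229L, 230L)),
  list(2L,  "Corpus Callosum Area",    c(218L, 219L, 220L)),
  list(3L,  "Other Fibretracts",       c(215L, 233L, 237L, 239L, 240L, 241L, 242L, 243L,
                                         244L, 247L, 248L, 251L, 252L, 253L)),
  list(4L,  "Cerebellar Vermis",       161L),
  list(5L,  "Ventricular System",      c(201L, 203L, 204L, 211L, 212L)),
  list(6L,  "Cerebellar Hemispheres",  c(179L, 180L)),
  list(7L,  "Hypothalamus",            c(109L, 110L, 121L)),
  list(8L,  "Rombocephalon",           c(151L, 153L)),
  list(9L,  "Mesencephalon",           c(127L, 129L, 130L, 133L, 134L, 135L, 136L, 139L,
                                         140L, 141L, 142L)),
  list(10L, "Thalamus",                c(83L, 84L)),
  list(11L, "Allocortex",              c(25L, 26L, 27L, 28L)),
  list(12L, "Hippocampal Area",        c(31L, 32L, 43L, 44L, 45L, 46L)),
  list(13L, "Deep Cortex",             c(53L, 54L, 55L, 56L)),
  list(14L, "Basal Ganglia",           c(69L, 70L, 71L, 72L, 75L, 76L)),
  list(15L, "Septum, Basal Forebrain", c(77L, 78L)),
  list(16L, "Isocortex",               c(5L, 6L, 7L, 8L, 9L, 10L, 11L, 12L, 13L, 14L,
                                         15L, 16L, 17L, 18L, 19L, 20L)))

build_default_macro_map <- function() {
  macros <- lapply(.default_macro_rows, function(r)
    list(name = r[[2]], members = r[[3]]))
  names(macros) <- vapply(.default_macro_rows, function(r)
    as.character(r[[1]]), "")
  macro_region_map(macros)
}
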