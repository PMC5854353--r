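# Loaded once per test run: both data layers and the curated keys.
ds <- load_reference()
ds_printed <- load_reference(layer = "as_printed")
keys <- load_keys(ds)
keys_printed <- load_keys(ds_printed, layer = "as_printed")
myzaphis_spp <- genus_species(ds, "Myzaphis")

# random partial specimen drawn from a profile, for property-style tests
random_specimen <- function(ds, taxon, morph, seed, keep = 0.7) {
  g <- generate_specimens(ds, 1, taxon, morph, mode = "table_only", seed = seed)
  corrupt_specimens(g$specimens, missing_fraction = 1 - keep, seed = seed + 1)[[1]]
}
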