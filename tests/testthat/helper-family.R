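# Shared synthetic fixtures, built once per test run and memoised.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# Small family for fast unit tests: 6 loci + identical pair + retrocopy + NR1.
small_family <- function() fixture("small_family", function() {
  simulate_locus_family(simulation_config(
    n_loci = 6L, reads_total = 0L, n_samples = 2L,
    mixing_proportions = c(0.5, 0.2, 0.15, 0.05, 0.05, 0.05), seed = 101L))
})

gag_definition <- function(family) {
  amplicon_definition(
    "gag",
    primer_set("gag", family$primers$gag$forward,
               family$primers$gag$reverse, max_mismatches = 1L),
    expected_lengths = list("1" = c(600L, 640L), "2" = c(600L, 640L)))
}

small_profile <- function() fixture("small_profile", function() {
  fam <- small_family()
  diagnostic_sites(extract_amplicons(fam$registry, gag_definition(fam)))
})

# Full-size family under the default study conditions (20 loci, 820 reads).
study_family <- function() fixture("study_family", function() {
  simulate_locus_family(simulation_config(seed = 8675309L))
})

study_profile <- function() fixture("study_profile", function() {
  fam <- study_family()
  extract_amplicons(fam$registry, gag_definition(fam))
})

# Env 5' region reference (type 2) with the indel segment annotated.
env_region_reference <- function(family) {
  ly <- family$layout
  anc <- family$ancestor
  ref <- substr(anc, ly$env_start, ly$env_start + 700L)
  attr(ref, "indel_segment") <- ly$segment - ly$env_start + 1L
  ref
}

extdata <- function(f) system.file("extdata", f, package = "hml2profiler")
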