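# Shared fixtures, built once per test run and cached. Everything derives
# from fixed seeds, so the suite is reproducible.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

get_ref_set <- function() fixture("ref_set", function() hml2_reference_set())

# The curated-set stand-in under the default study conditions (704/828/256
# raw elements, 43/62/194 full-length) -- the heavyweight fixture.
get_element_set <- function() fixture("element_set", function()
  simulate_element_set(get_ref_set(), seed = 20220718 %% 1000L))

get_kept_elements <- function() fixture("kept", function() {
  es <- get_element_set()
  lapply(es$elements, function(l)
    l[es$truth$kept[match(names(l), es$truth$id)]])
})

# Extracted -263..0 sections of the kept elements, per subtype.
get_section_seqs <- function() fixture("sections", function() {
  rs <- get_ref_set()
  s3 <- ltr_sections()[3, ]
  lapply(get_kept_elements(), function(els)
    extract_sections(els, rs$frame_ref, rs$tss_index, s3)$seqs)
})

get_genome_sim <- function() fixture("genome_sim", function()
  simulate_genome(get_ref_set(), seed = 42))
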