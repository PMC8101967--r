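# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# a small two-family genome used by several suites
two_family_sim <- function() fixture("two_family_sim", function() {
  simulate_genome(list(
    family_spec("F1", tir_length = 30L, tsd_length = 8L, n_copies = 3L,
                orf_length = 300L),
    family_spec("F2", tir_length = 24L, tsd_length = 9L, n_copies = 3L,
                orf_length = 280L, per_copy_divergence = 0.02)),
    background_length = 40000L, seed = 11L)
})

two_family_report <- function() fixture("two_family_report", function() {
  sim <- two_family_sim()
  run_pipeline(sim$genome,
               setNames(sim$truth$proteins, paste0("q_", names(sim$truth$proteins))))
})

# extract the planted element and its flanks straight from the truth table
truth_element <- function(sim, i, slack = 0L, flank = 40L) {
  tr <- sim$truth$copies[i, ]
  contig <- sim$genome[[tr$contig]]
  list(element = substr(contig, tr$start + 1L - slack, tr$end + slack),
       flank5 = substr(contig, tr$start - flank + 1L, tr$start),
       flank3 = substr(contig, tr$end + 1L, tr$end + flank),
       truth = tr)
}
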