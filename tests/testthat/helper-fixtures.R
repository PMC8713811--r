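# Shared fixtures.  The default schema is loaded once per test run.
SCHEMA <- default_schema()
CLASSES6 <- c("I_HEAVY", "B2M", "IIA", "IIB", "WA", "WB")

counts_per_class <- function(n) setNames(rep(as.integer(n), 6L), CLASSES6)

# Write a schema list as JSON and load it through the validator.
schema_from_list <- function(x) {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  load_schema(path)
}

# A minimal toy schema: one 10-column frame, two symmetric classes that each
# claim one residue at one column (useful for tie and enumeration tests).
toy_schema_list <- function(signatures) {
  list(version = "toy",
       frames = list(list(name = "IG_C1", length = 10L,
                          consensus = "ARNDGHKMST", numbering_origin = 1L)),
       signatures = signatures)
}

toy_sig <- function(position, allowed, class, weight = 1, role = "CORE") {
  list(frame = "IG_C1", position = position, allowed_residues = allowed,
       chain_class = class, role = role, weight = weight)
}

# Simulated chains classified in one call.
simulate_and_classify <- function(n_per_class, mu, seed, tau = 0.15) {
  cfg <- sim_config(seed = seed, mu = mu, counts = counts_per_class(n_per_class))
  b <- make_chains(cfg, SCHEMA)
  r <- classify_sequences(b$sequences, SCHEMA, tau = tau)
  list(truth = b$truth, table = r$table, calls = r$calls,
       accuracy = mean(r$table$label == b$truth$label))
}

# One noise-free chain of a class, segmented and classified.
call_for <- function(label, seed = 1L, mu = 0) {
  ch <- make_chain(label, sim_config(seed = seed, mu = mu), SCHEMA,
                   chain_id = label)
  arch <- segment_chain(ch$sequence, SCHEMA, chain_id = label)
  classify_chain(arch, ch$sequence, SCHEMA)
}
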