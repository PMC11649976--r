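# Shared, memoised test objects: the canonical template and the packaged
# fixture set are loaded once per test run.
.cache <- new.env()

tpl <- function() {
  if (is.null(.cache$t)) .cache$t <- load_template()
  .cache$t
}

fixtures <- function() {
  if (is.null(.cache$fx)) {
    .cache$fx <- load_fixture_set(template = tpl())
    names(.cache$fx) <- vapply(.cache$fx, `[[`, "", "name")
  }
  .cache$fx
}

fixture <- function(name) {
  fx <- fixtures()
  rec <- fx[[name]]
  if (is.null(rec)) stop("no fixture named ", name)
  rec
}

# a small programmatic ligand: a chain of n carbons
carbon_chain <- function(n, name = paste0("chain", n)) {
  atoms <- data.frame(element = rep("C", n), charge = 0L, aromatic = FALSE,
                      in_ring = FALSE, rigid_block = 0L,
                      implicit_h = c(3L, rep(2L, max(0L, n - 2L)),
                                     if (n > 1L) 3L),
                      stringsAsFactors = FALSE)
  bonds <- if (n > 1L)
    data.frame(a1 = seq_len(n - 1L), a2 = 2:n, order = 1L)
  else data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  g <- ligand_graph(name, atoms, bonds)
  g$rings <- list()
  tag_functional_groups(g)
}
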