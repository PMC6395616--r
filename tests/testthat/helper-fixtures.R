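# toy fixtures shared across test files

toy_genes <- function(n = 10, chrom = "c1", prefix = "g", genome_id = "toy",
                      strand = "+") {
  gene_table(paste0(prefix, seq_len(n)), chrom,
             (seq_len(n) - 1L) * 1000L, (seq_len(n) - 1L) * 1000L + 500L,
             rep(strand, length.out = n), genome_id = genome_id)
}

toy_hits <- function(q, s, evalue = 1e-20, bitscore = 100) {
  data.frame(query = q, subject = s,
             evalue = rep_len(evalue, length(q)),
             bitscore = rep_len(bitscore, length(q)),
             stringsAsFactors = FALSE)
}

# anchors a_i -> b_i for two toy genomes; orders given on each side
diagonal_hits <- function(orders_a, orders_b, evalue = 1e-20) {
  toy_hits(paste0("a", orders_a + 1L), paste0("b", orders_b + 1L), evalue)
}

small_sim <- function(seed = 1, n = 800, ...) {
  simulate_genomes(simulation_config(seed = seed, n_outgroup_genes = n,
                                     ancient_segments = 6L,
                                     rearrangement_events = 2L, ...))
}

# gene-label accuracy against the planted copies: within each region pair
# (up to the swap the singleton rule cannot determine) and globally
label_accuracy <- function(sim, rp, asg) {
  copy <- sim$truth$copy[match(asg$gene_id, sim$truth$gene_id)]
  og2pair <- integer(0)
  for (k in seq_len(nrow(rp$pairs))) og2pair[rp$claimed[[k]]] <- k
  pg <- og2pair[asg$outgroup_anchor]
  assigned <- asg$subgenome != "unassigned" & copy %in% c("A", "B") &
    !is.na(pg)
  ok <- 0; ntot <- 0
  for (k in seq_len(nrow(rp$pairs))) {
    sel <- which(assigned & pg == k)
    if (!length(sel)) next
    m1 <- mean((asg$subgenome[sel] == "subgenome1") == (copy[sel] == "A"))
    ok <- ok + max(m1, 1 - m1) * length(sel)
    ntot <- ntot + length(sel)
  }
  g1 <- mean((asg$subgenome[assigned] == "subgenome1") ==
               (copy[assigned] == "A"))
  list(pair = ok / ntot, global = max(g1, 1 - g1), n = ntot)
}

# recent blocks + assignment for a small simulation
small_assignment <- function(sim, seed = 1) {
  blocks <- filter_blocks(chain_anchors(sim$hits_dup_out, sim$genes_dup,
                                        sim$genes_out))
  blocks <- block_ks(blocks, sim$kaks_dup_out)
  mix <- fit_ks_mixture(blocks$blocks$median_ks, k = 2, seed = seed)
  recent <- classify_blocks_by_ks(blocks, mix)$recent
  rp <- pair_homologous_regions(recent, sim$genes_out)
  list(recent = recent, rp = rp,
       assignment = assign_subgenomes(rp, recent, sim$genes_dup))
}
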