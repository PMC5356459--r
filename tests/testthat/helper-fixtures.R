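# Shared helpers: canonical keys for set comparisons, a BFS/igraph
# connectivity oracle, and profile perturbation used to build
# contradictory inputs from compatible ones.

setkey <- function(x) paste(sort(x), collapse = "\r")

cluster_keys <- function(tree) sort(vapply(slt_clusters(tree), setkey, ""))

pairkeys <- function(m) if (nrow(m)) sort(paste(m[, 1], m[, 2], sep = "\r")) else character(0)

pos_keys <- function(position) vapply(position, function(x) paste(sort(x), collapse = ","), "")

# Membership vector of components of an edge list on n vertices.
bfs_membership <- function(n, edges) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$membership
}

# Make a compatible profile contradictory by appending a two-label
# ancestor cycle over labels already present (keeps the display graph
# connected to the rest).
perturb_incompatible <- function(profile, seed) {
  labs <- profile$label_universe
  set.seed(seed)
  pick <- sample(labs, 2L)
  cyc <- read_profile(text = sprintf("(%s)%s; (%s)%s;",
                                     pick[2], pick[1], pick[1], pick[2]))
  new_profile(c(profile$trees, cyc$trees))
}

expected_supertree <- function() {
  parse_newick("((((b,c)'4+a',d)g,e)3,(h,i)f)'1+2';", multi_sep = "+")
}
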