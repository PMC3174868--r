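# Tiny molecules built in code, used across the suite.

ethanol <- function() {
  constitution(
    atoms = data.frame(id = c("C1", "C2", "O*1"), element = c("C", "C", "O"),
                       n_h = c(3L, 2L, 1L)),
    bonds = data.frame(i = c(1, 2), j = c(2, 3), order = 1)
  )
}

dimethyl_ether <- function() {
  constitution(
    atoms = data.frame(id = c("C1", "C2", "O*1"), element = c("C", "C", "O"),
                       n_h = c(3L, 3L, 0L)),
    bonds = data.frame(i = c(1, 2), j = c(3, 3), order = 1)
  )
}

methane <- function() {
  constitution(atoms = data.frame(id = "C1", element = "C", n_h = 4L),
               bonds = data.frame())
}

propane <- function() {
  constitution(
    atoms = data.frame(id = c("C1", "C2", "C3"), element = "C",
                       n_h = c(3L, 2L, 3L)),
    bonds = data.frame(i = c(1, 2), j = c(2, 3), order = 1)
  )
}

benzene <- function(flip = FALSE) {
  ord <- if (flip) c(2L, 1L) else c(1L, 2L)
  constitution(
    atoms = data.frame(element = rep("C", 6), n_h = rep(1L, 6)),
    bonds = data.frame(i = 1:6, j = c(2:6, 1), order = rep(ord, 3))
  )
}

# random relabeling of a constitution's atoms (graph unchanged)
permute_atoms <- function(m, perm) {
  inv <- order(perm)
  constitution(
    atoms = m$atoms[perm, ],
    bonds = data.frame(i = inv[m$bonds$i], j = inv[m$bonds$j],
                       order = m$bonds$order)
  )
}

# specs + compiled constraints for a structure's dropout-free correlations
toy_problem <- function(m, experiments = c("cosy", "hmbc")) {
  corr <- forward_correlations(m, forward_config(experiments))
  specs <- as_atom_specs(m)
  list(
    formula = constitution_formula(m),
    specs = specs,
    corr = corr,
    constraints = compile_constraints(corr, specs)
  )
}
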