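#' Atom-contribution logP (ALOGP)
#'
#' Ghose–Crippen style octanol/water partition coefficient in the
#' Wildman–Crippen parameterisation: every atom (hydrogens included) is
#' assigned to one of a fixed set of element/environment classes and the
#' published per-class contributions are summed. Classification is by
#' first-matching rule over the bonding environment (aromaticity, attached
#' hydrogens, neighbouring elements, bond orders, formal charge). An atom
#' outside the classifiable element set (C, H, N, O, S, P, halogens) raises
#' an error, which [compute_descriptors()] converts into a per-record
#' descriptor failure — never a silent zero.
#'
#' @name alogp
NULL

# per-atom neighbour info used by the typing rules
.crippen_env <- function(g) {
  n <- g$n_atoms
  env <- replicate(n, list(nbr = integer(0), order = numeric(0),
                           arom_bond = logical(0)), simplify = FALSE)
  if (nrow(g$bonds)) {
    for (i in seq_len(nrow(g$bonds))) {
      b <- g$bonds[i, ]
      env[[b$a1]]$nbr <- c(env[[b$a1]]$nbr, b$a2)
      env[[b$a1]]$order <- c(env[[b$a1]]$order, b$order)
      env[[b$a1]]$arom_bond <- c(env[[b$a1]]$arom_bond, b$aromatic)
      env[[b$a2]]$nbr <- c(env[[b$a2]]$nbr, b$a1)
      env[[b$a2]]$order <- c(env[[b$a2]]$order, b$order)
      env[[b$a2]]$arom_bond <- c(env[[b$a2]]$arom_bond, b$aromatic)
    }
  }
  env
}

# contribution of heavy atom i (see the Wildman-Crippen class values)
.crippen_heavy <- function(g, env, i) {
  e <- g$element[i]; ar <- g$aromatic[i]; nh <- g$nh[i]; ch <- g$charge[i]
  nb <- env[[i]]$nbr; ord <- env[[i]]$order; arb <- env[[i]]$arom_bond
  nbr_el <- g$element[nb]; nbr_ar <- g$aromatic[nb]
  plain <- !arb                      # non-aromatic bonds
  n_dbl <- sum(plain & ord == 2); n_trp <- sum(plain & ord == 3)
  het <- c("N", "O", "P", "S", "F", "Cl", "Br", "I")

  if (e == "C") {
    if (ar) {
      if (sum(arb) >= 3) return(0.2955)                      # fusion carbon
      if (nh >= 1) return(0.1581)                            # aromatic CH
      sub <- which(plain)
      if (!length(sub)) return(0.08129)
      s1 <- sub[1]
      if (ord[s1] == 2) return(-0.8186)                      # exocyclic =X
      x <- nb[s1]
      if (g$aromatic[x]) return(0.2713)                      # biaryl link
      return(switch(g$element[x],
        C = 0.136, N = 0.4619, O = 0.5437, S = 0.1893,
        F = 0.0, Cl = 0.245, Br = 0.198, I = 0.0, -0.5443))
    }
    if (n_trp >= 1) return(0.0017)                           # sp carbon
    if (n_dbl >= 1) {
      partners <- nb[plain & ord == 2]
      if (any(g$element[partners] != "C")) return(-0.2783)   # C=heteroatom
      if (any(g$aromatic[partners]) || any(nbr_ar)) return(0.264)
      return(0.1551)                                         # aliphatic C=C
    }
    if (any(nbr_ar)) {                                       # benzylic-type
      if (nh == 3) return(if (any(nbr_ar & nbr_el == "C")) 0.08452 else -0.1444)
      if (nh == 2) return(-0.0516)
      if (nh == 1) return(0.1193)
      return(-0.0967)
    }
    if (any(nbr_el %in% het)) return(if (nh >= 2) -0.2035 else -0.2051)
    if (all(nbr_el %in% "C")) return(if (nh >= 2) 0.1441 else 0.0)
    return(0.2148)                                           # exotic neighbour
  }

  if (e == "N") {
    if (ch != 0) {
      if (ar) return(-1.119)
      if (nh >= 1) return(-1.950)
      if (ch == 1L && length(nb) >= 3) return(-0.3396)       # quaternary / nitro
      return(0.2887)
    }
    if (ar) return(-0.3239)
    if (n_trp >= 1) return(0.01508)
    if (n_dbl >= 1) return(if (nh >= 1) 0.08387 else 0.1836)
    if (nh == 2 && length(nb)) return(if (any(nbr_ar)) -1.027 else -1.019)
    if (nh == 1 && length(nb) == 2) return(if (any(nbr_ar)) -0.5188 else -0.7096)
    if (nh == 0 && length(nb) == 3) return(if (any(nbr_ar)) -0.4458 else -0.3187)
    return(-0.4806)
  }

  if (e == "O") {
    if (ar) return(0.1552)
    if (nh >= 1) return(-0.2893)
    if (ch == -1L && length(nb)) {
      x <- nb[1]
      if (g$element[x] == "N") return(0.0335)
      if (g$element[x] == "S") return(-0.3339)
      if (g$element[x] == "C") {
        xo <- env[[x]]
        if (any(!xo$arom_bond & xo$order == 2 & g$element[xo$nbr] == "O"))
          return(-1.326)                                     # carboxylate
      }
      return(-1.189)
    }
    if (n_dbl >= 1) {
      p <- nb[plain & ord == 2][1]
      if (g$aromatic[p]) return(0.1788)                      # O=c
      pe <- g$element[p]
      if (pe %in% c("N", "O")) return(0.0335)
      if (pe == "S") return(-0.3339)
      if (pe == "C") {
        po <- env[[p]]
        others <- po$nbr != i
        if (sum(!po$arom_bond & po$order >= 2 & others) >= 1) return(-0.1188)
        if (any(g$aromatic[po$nbr])) return(0.1129)          # aryl carbonyl
        if (sum(g$element[po$nbr[others]] != "C") >= 2) return(0.4833)
        return(-0.1526)                                      # plain carbonyl
      }
      return(-0.1188)
    }
    if (length(nb) == 2) return(if (any(nbr_ar)) -0.4195 else -0.0684)
    return(-0.1188)
  }

  if (e == "S") {
    if (ar) return(0.6237)
    if (ch != 0 || any(plain & ord == 2 & nbr_el %in% c("N", "O", "P", "S")))
      return(-0.0024)
    return(0.6482)
  }
  if (e == "P") return(0.8612)
  if (e %in% c("F", "Cl", "Br", "I")) {
    if (ch != 0) return(-2.996)
    return(switch(e, F = 0.4202, Cl = 0.6895, Br = 0.8456, I = 0.8857))
  }
  stop("atom ", i, " (", e, ") is not classifiable for ALOGP", call. = FALSE)
}

# contribution of the nh hydrogens attached to heavy atom i
.crippen_hydrogens <- function(g, env, i) {
  nh <- g$nh[i]
  if (nh == 0L) return(0)
  e <- g$element[i]
  per_h <- if (e == "C") 0.1230
  else if (e == "N") 0.2142
  else if (e == "S") -0.2677
  else if (e == "O") {
    nb <- env[[i]]$nbr
    if (!length(nb)) -0.2677                                  # water
    else {
      b <- nb[1]; be <- g$element[b]
      if (be == "N") 0.2142
      else if (be %in% c("O", "S")) 0.2980
      else if (be == "C") {
        bo <- env[[b]]
        acid_like <- any(!bo$arom_bond & bo$order == 2 &
                           g$element[bo$nbr] %in% c("C", "N", "O", "S"))
        if (acid_like) 0.2980 else -0.2677
      } else -0.2677
    }
  } else 0.1125
  nh * per_h
}

#' Compute the atom-contribution logP
#'
#' @inheritParams estate_indices
#' @return the summed contribution over all atoms, hydrogens included.
#' @examples
#' alogp("CCO")       # about 0.0
#' @export
alogp <- function(mol) {
  g <- .as_graph(mol)
  env <- .crippen_env(g)
  total <- 0
  for (i in seq_len(g$n_atoms)) {
    total <- total + .crippen_heavy(g, env, i) + .crippen_hydrogens(g, env, i)
  }
  total
}
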