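# Fixtures and independent oracles used across the suite.

siteTableFrom <- function(doses) {
  new("SiteDoseTable", doses = doses, missingSites = integer(),
      flags = character())
}

uniformSiteTable <- function(value, registry = loadTissueRegistry()) {
  ids <- registrySites(registry)$site_id
  siteTableFrom(stats::setNames(rep(value, length(ids)), ids))
}

organTableFrom <- function(H, registry) {
  cat_of <- vapply(registry@tissues, function(t) t@category, character(1))
  names(cat_of) <- vapply(registry@tissues, function(t) t@tissueName,
                          character(1))
  new("OrganDoseTable", table = data.frame(
    tissue = names(H), H_mSv = unname(H),
    category = unname(cat_of[names(H)]), provenance = ""))
}

# Independent brute-force recomputation of E = sum W_T H_T (+ remainder
# mean under the shared weight), written as explicit accumulation loops.
bruteForceEffectiveDoseUSv <- function(H, registry) {
  total <- 0
  rem <- c()
  for (t in registry@tissues) {
    h <- H[[t@tissueName]]
    if (t@category == "weighted_tissue") {
      total <- total + t@weightingFactor * h
    } else {
      rem <- c(rem, h)
    }
  }
  if (length(rem)) total <- total + registry@remainderWeight *
      sum(rem) / length(rem)
  1000 * total
}

# small randomized registry over sites 1..6 for property tests
randomSmallRegistry <- function(seed) {
  set.seed(seed)
  sites <- data.frame(site_id = 1:6,
                      anatomical_label = paste("site", 1:6),
                      phantom_slice = 1:6)
  mkTissue <- function(name, w, category, subsites,
                       aggregate = "mean") {
    new("TissueEntry", tissueName = name, weightingFactor = w,
        category = category, aggregate = aggregate, applyMeacr = FALSE,
        subsites = subsites)
  }
  nW <- sample(2:4, 1)
  tissues <- lapply(seq_len(nW), function(i) {
    mkTissue(paste0("tw", i), round(stats::runif(1, 0.005, 0.12), 3),
             "weighted_tissue",
             list(list(name = paste0("tw", i),
                       fraction = round(stats::runif(1, 0.05, 1), 2),
                       sites = sample(1:6, sample(1:3, 1)))))
  })
  dist <- mkTissue("dist", round(stats::runif(1, 0.005, 0.12), 3),
                   "weighted_tissue",
                   list(list(name = "a", fraction = 0.1, sites = c(1L, 2L)),
                        list(name = "b", fraction = 0.05, sites = 3L)),
                   aggregate = "weighted_sum")
  rem <- lapply(1:2, function(i)
    mkTissue(paste0("rc", i), NA_real_, "remainder_component",
             list(list(name = paste0("rc", i),
                       fraction = round(stats::runif(1, 0.05, 1), 2),
                       sites = sample(1:6, 2)))))
  tissues <- c(tissues, list(dist), rem)
  names(tissues) <- vapply(tissues, function(t) t@tissueName, character(1))
  new("TissueRegistry", sites = sites, tissues = tissues,
      remainderWeight = 0.12)
}

# uniform slab of soft tissue, normal to x, for attenuation oracles
slabPhantom <- function(thicknessCm, halfSide = 10) {
  organs <- data.frame(
    id = "slab", organ = "slab", primitive = "box",
    material = "soft_tissue", cx = 0, cy = 0, cz = 0,
    d1 = thicknessCm / 2, d2 = halfSide, d3 = halfSide,
    mass_g = thicknessCm * (2 * halfSide)^2 * 1.06)
  new("PhantomGeometry", organs = organs, referencePoint = c(0, 0, 0),
      boundCenter = c(0, 0, 0),
      boundRadius = sqrt((thicknessCm / 2)^2 + 2 * halfSide^2) + 0.5)
}

# a pencil beam along +x entering the slab face
pencilBeam <- function(n, energyKeV, nBatches = 10) {
  list(pos = cbind(rep(-30, n), 0, 0),
       dir = cbind(rep(1, n), 0, 0),
       E = rep(energyKeV, n),
       batch = rep_len(seq_len(nBatches), n))
}

mkEffectiveDose <- function(E, label) {
  new("EffectiveDoseResult", effectiveDoseUSv = E,
      perTissueUSv = c(total = E), methodLabel = label)
}

# a fixed, plausible ground-truth site-dose map (mGy) for closed-loop runs:
# highest near the oral cavity / salivary region, lowest at distal brain
fixtureSiteTruth <- function(registry = loadTissueRegistry()) {
  ids <- registrySites(registry)$site_id
  base <- c(`1` = 0.35, `2` = 0.30, `3` = 0.25, `4` = 0.20, `5` = 0.40,
            `6` = 0.55, `7` = 0.90, `8` = 0.90, `9` = 0.45, `10` = 0.35,
            `11` = 1.60, `12` = 2.10, `13` = 1.20, `14` = 2.60,
            `15` = 2.60, `16` = 0.30, `17` = 2.20, `18` = 2.20,
            `19` = 0.80, `20` = 0.60, `21` = 0.70, `22` = 0.70)
  base[as.character(ids)]
}

# linear response coefficients of E with respect to each site dose,
# obtained by unit-impulse evaluation (the pipeline is linear)
siteCoefficients <- function(registry, kVp) {
  ids <- registrySites(registry)$site_id
  vapply(ids, function(s) {
    d <- stats::setNames(numeric(length(ids)), ids)
    d[as.character(s)] <- 1
    od <- organDoses(siteTableFrom(d), registry, kVp)
    effectiveDoseUSv(effectiveDose(od, registry))
  }, numeric(1))
}
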