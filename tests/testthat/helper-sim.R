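# Shared fixtures: small simulations reused across test files, built once.

`%&&%` <- function(a, b) paste(a, b)

.fixtures <- new.env()

# moderate pedigree with inflated mutation rates so every stage has events
smallSim <- function() {
  if (is.null(.fixtures$small)) {
    .fixtures$small <- simulatePedigree(simConfig(
      seed = 42L, nChromosomes = 2L, chromLengthBp = 5e6,
      snvDensity = 2e-4, germlineSnvRate = 1e-7, pzmRate = 2e-8,
      trCatalogSize = 300L, trMutationRate = 2e-3))
  }
  .fixtures$small
}

g3Children <- function(sim) {
  m <- members(sim$pedigree)
  m$id[!is.na(m$father) & m$father == "F1" & m$mother == "M1"]
}

# noiseless per-platform profile helpers
cleanProfiles <- function(depth = 30) {
  pr <- defaultPlatformProfiles()
  pr$depth <- depth
  pr$baseError <- 0
  pr$lowBqFraction <- 0
  pr$mqPassRate <- 1
  pr
}
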