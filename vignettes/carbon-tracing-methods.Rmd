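---
title: "Methods: carbon-atom fate simulation and pathway attribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: carbon-atom fate simulation and pathway attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carbontrace)
```

This vignette documents the model behind `carbontrace`: the atom-transition
network and its conventions, the deterministic label-propagation simulator,
the inversion of combined GC-MS and NMR observables, the statistics, the
synthetic study generator, and the numerical and design choices behind each.

## The atom-transition network

Metabolite labelling states are binary pattern strings, carbon 1 first
(`"0110"` = a 4-carbon molecule with ¹³C at C2 and C3). Carbon numbering
follows the standard biochemical convention throughout: glucose C1 is the
aldehyde carbon, pyruvate C1 the carboxyl, aspartate and glutamate C1 the
alpha-carboxyl. Every reaction carries an explicit atom map — a bijection
from substrate carbons to product carbons, with CO₂-released carbons mapped
to a CO₂ product — so label is conserved by construction and the whole
convention is auditable via `build_default_network()$metabolites` and the
map tokens themselves (`write_network()` prints them in a documented
plain-text grammar).

Key maps, in the fixed OAA/acetyl frame used by the cycle code
(`OAA = abcd`, `acetyl-CoA = ef` with `e` the carbonyl carbon):

* citrate synthase: `citrate = (d, c, b, f, e, a)`;
* isocitrate dehydrogenase releases citrate C6 (= OAA C1) as CO₂;
* alpha-KG dehydrogenase releases aKG C1 (= OAA C4) as CO₂, so one full round
  removes exactly the two OAA-derived end carbons and first-round acetyl
  carbons always survive into the next OAA;
* succinate and fumarate are symmetric: their carbon order is scrambled
  50/50 on formation (applying the scrambling twice equals applying it once;
  this is tested). Citrate is treated as prochiral — aconitase handles it
  asymmetrically — per standard biochemistry.

Two direction-of-travel consequences anchor the attribution logic and are
verified against an independent brute-force path enumeration written
directly from the textbook transitions: PDH-derived acetyl units on an
unlabelled OAA pool give the scrambled aspartate pair `1100 + 0011`, and
pyruvate-carboxylase entry gives `0110` (pyruvate C1–C3 onto OAA C1–C3,
unlabelled CO₂ onto C4; the CO₂ pool is treated as unlabelled by default,
which is exactly what makes C4 silent).

One documented wrinkle: descriptions of the reverse-glycolysis route
sometimes call glycolytic GAP "1,2-labelled" from [1,2-¹³C]glucose, whereas
the standard maps place the label on GAP carbons 2,3 (glucose C1 goes to GAP
C3 via DHAP and TPI). Both conventions deliver label to F6P **carbon 5** on
aldolase reversal, so the reverse-flux detector is unaffected; we follow the
standard maps.

## The simulator

`simulate_labelling()` is deterministic mixture arithmetic over pattern
supports — no random numbers. Distributions are pruned below 1e-12 and
renormalised to keep supports small.

**Upper glycolysis and PPP.** A fraction `f_oxppp` of glucose flux takes the
oxidative PPP, modelled as a lumped operation: glucose C1 leaves as CO₂; the
three resulting pentoses recombine through the canonical transketolase /
transaldolase maps into two F6P and one GAP, with recombination partners
drawn independently from the pentose pool (well-mixed assumption). The
transketolase-1 products (S7P and GAP) stay jointly tracked into
transaldolase because they share carbons of one donor pentose. Molar
bookkeeping is per unit glucose: direct glycolysis contributes `1 − f` F6P,
the PPP `2/3 f` F6P and `1/3 f` GAP.

**Trioses and reverse glycolysis.** Aldolase cleaves FBP into DHAP (C1–C3)
and GAP (C4–C6); TPI is assumed fully equilibrated, so the DHAP pool is the
carbon-reversed GAP pool. `f_reverse` is the fraction of the F6P pool formed
by reverse aldolase from independent draws of the two triose pools — the
route that places label on F6P carbon 5. Reverse-formed F6P that recleaves
returns the same trioses, so the triose pool itself is unchanged by the
reverse cycle at steady state; the simulator therefore derives trioses from
forward flux only, without a fixed point.

**TCA rounds.** The cycle state is the OAA pool. The anaplerotic entry pool
mixes glutamine-derived OAA (weight `f_gln`; glutamine passes glutamate,
aKG, the aKG dehydrogenase decarboxylation and the succinate scrambling
before reaching OAA), PC-derived OAA (`(1 − f_gln) f_pc`) and pre-existing
unlabelled OAA (the remainder). Each round condenses the current OAA pool
with acetyl-CoA drawn from the same pyruvate-derived distribution
(well-mixed), decarboxylates twice, scrambles at succinate, and returns the
next OAA pool. The number of rounds before exit to aspartate is geometric
with per-round probability `turn_exit`, truncated at `n_max_turns`
(default 4) with the residual mass folded into the final round. Exit at
round zero — anaplerotic OAA leaving before any condensation — is what makes
the PC pattern visible in aspartate. Cycle intermediates (citrate, aKG,
succinate, malate) are reported as occupancy-weighted mixtures over rounds.
How many rounds a real "multi-round" pool represents is not observable from
a single endpoint; `n_max_turns` is exposed, and with the default
`turn_exit` values the round-4 residual carries well under 10% of the pool,
so results are insensitive to the cap.

**Pyruvate recycling (`f_pyr_cycle`).** Under the standard maps, a round with
unlabelled acetyl-CoA removes exactly the two labelled end carbons of an
m+4 OAA, so [U-¹³C]glutamine can only produce aspartate m+4, m+2, m+1 —
never m+3. The m+3 species (`0111 + 1110`) require *labelled* acetyl-CoA
condensing with a scrambled m+2 OAA, i.e. glutamine carbon returning to
acetyl-CoA through malate → pyruvate (malic enzyme) → PDH. The simulator
models this with `f_pyr_cycle`, the fraction of the pyruvate pool
regenerated from cycle malate, resolved by fixed-point iteration
(L1 tolerance 1e-12, capped at 50 iterations; convergence is geometric in
`f_pyr_cycle`). The default is 0 — recycling is switched on only where the
biology calls for it (the NAD⁺-depleted condition of the synthetic
scenario).

**Steady state.** Pools are at isotopic steady state within a condition;
there are no time-course kinetics. A single labelling endpoint is modelled.

## Observables

`mid_of()` collapses patterns by mass. `multiplets_of()` does the HSQC
bookkeeping: for each carbon, the pool fractions in which it is unlabelled,
or labelled with unlabelled/lower/higher/both chain neighbours labelled —
the singlet, two doublet and doublet-of-doublets components. Only the
pattern-level combinatorics is modelled; J-coupling constants, chemical
shifts and spectral simulation are out of scope. Terminal carbons have
structural zeros in the impossible doublet component.

## Inversion and identifiability

Both observables are linear in the isotopomer distribution, so inversion is
constrained linear least squares over the 2ⁿ simplex (n ≤ 6 here, so the
full pattern basis is tractable and no sparsity prior is needed):
Lawson–Hanson NNLS with an augmented sum-to-one row (weight 10; the residual
is reported on the observables only, and on any forward-generated input the
solution is exact, so the augmentation weight is immaterial there).
Infeasible inputs — observables off their own simplex beyond `tol`, or
nonzero mass in a terminal carbon's impossible doublet — raise explicit
errors rather than being silently projected.

Identifiability is the interesting part. The stacked design matrix has full
column rank for n ≤ 3, but for n = 4 its constrained nullspace is
3-dimensional: some positional distributions cannot be distinguished by
(MID, multiplet) data at all. `resolve_isotopomers()` therefore computes the
nullspace and flags a fit as non-unique when a feasible flat direction
exists at the optimum (a direction nonnegative on the active, zero-weight
patterns — searched by quasi-Newton over the nullspace from deterministic
starts; with no active patterns any nullspace direction is feasible). The
flag is reported, never hidden.

Crucially, all pathway-class indicator functionals of the default aspartate
rule set are numerically orthogonal to that nullspace — verified to 1e-9 in
the tests — so any exact-fitting solution yields identical class weights:
pathway attribution is identifiable even where the positional distribution
is not. This is why the noiseless round trip simulate → observe → resolve →
attribute recovers class weights to machine precision across the parameter
grid in the acceptance suite.

## Attribution rule sets

Class assignment is hard: each pattern belongs to exactly one class, classes
are pairwise disjoint, the all-zero pattern is its own "unlabelled" class,
and labelled patterns outside every class are reported under "other", never
dropped. The aspartate/[1,2-¹³C]glucose rule set uses the printed classes
(glycolysis `1100+0011`; TCA rounds + PPP `0100+0010, 1111, 0111+1110,
1000+0001`; PC `0110`) verbatim, including their biological ambiguity —
`0011` is reachable both by first-round PDH and by later rounds, and the
m+1/m+4 patterns of the TCA-rounds class are kept as one class without
splitting out a PPP-specific origin. The lactate rule set encodes the
standard [1,2-¹³C]glucose logic: glycolysis = carbons 2,3 (`011`), oxidative
PPP = carbon 3 only (`001`). The aspartate/[U-¹³C]glutamine rule set has a
first-pass class (`1111`) and a multi-round class enumerated from the atom
maps (all m+2/m+3 patterns reachable after two or more rounds, glutamine-
derived acetyl-CoA allowed); the enumeration is cross-checked in the tests
against the independent oracle.

The reverse-glycolysis detector is simply the total weight on F6P patterns
with carbon 5 labelled — equivalently one row of the multiplet design, which
is why it is identifiable directly from the HSQC table. It is zero under
forward-only flux and strictly increasing in `f_reverse` (property-tested).

## Statistics

* `nat_abundance_correct()` solves the lower-triangular binomial
  convolution (each non-tracer carbon carries ¹³C independently at natural
  abundance, default 0.011), clips tiny negatives and renormalises. The
  inverse property holds exactly on feasible inputs; severely infeasible
  MIDs (total negative mass beyond 0.05) error out.
* `anova_dunnett()` fits a one-way ANOVA and computes two-sided Dunnett
  adjusted p-values from the equicorrelated multivariate-t distribution
  (correlations `sqrt(n_i n_j / ((n_i + n_0)(n_j + n_0)))`, residual df),
  using `mvtnorm` quadrature pinned to a fixed internal seed so repeated
  calls agree; the same formula covers unbalanced designs, so no separate
  Monte-Carlo fallback is needed. With two groups it reduces exactly to the
  unadjusted two-sided t-test, and the null family-wise error calibrates to
  0.05 (both are tested; `multcomp::glht` serves as an independent
  cross-check in the test suite). Significance tiers follow the study's
  figure legends: `*` p < 0.05, `**` p < 0.01, `***` p < 0.005 — note the
  deliberately retained 0.005 (not 0.001) third tier.
* Ratios (`lac_pyr_m2_ratio()`, `pcr_cr_ratio()`, `fold_change()`,
  `normalize_to_pellet()`) are guarded arithmetic; all are invariant to
  pellet-weight normalisation applied to both sides.

## The synthetic study generator

`generate_dataset()` emulates the study design end to end: conditions
control / NR 4 h / NMN 4 h / NR 24 h / FK866 24 h / FK866 48 h /
FK866 48 h + NR 4 h; 6 replicates for C2C12 and 4 for primary myotubes; a
[1,2-¹³C]glucose arm and a [U-¹³C]glutamine arm. Noiseless observables come
from the simulator under each condition's pathway fractions; noise is
lognormal (mean-preserving, CV 0.15 by default) on positive observables and
a Dirichlet perturbation (concentration 1/CV²) on simplex observables, after
which MIDs are convolved with natural abundance. Raw values scale with a
replicate-level pellet weight so that `normalize_to_pellet()` has something
real to remove. Everything is deterministic given the seed.

Effect sizes stated numerically in the study are encoded exactly: NAD⁺
×0.05 at FK866 48 h (the 95% reduction), restored above control with NR;
NAM ×9 (NR) and ×1.8 (NMN). The remaining multipliers are qualitative in the
source ("significantly elevated/reduced") and are package assumptions,
chosen once at magnitudes typical for such experiments and not revisited:
MeNAM ×3 under NR in the C2C12 arm only; NAD⁺ ×0.25 at 24 h; PCr ×0.5 at
48 h; GAP and glycerol-3-P ×2 at 48 h only; citrate/aKG/malate ×0.5 at 48 h,
restored with NR; aspartate ×2 and pyruvate ×0.6 at 48 h. Pathway fractions
shift only at 48 h (reverse glycolysis 0 → 0.3, PC 0.15 → 0.3, turn exit
0.6 → 0.4, glutamine anaplerosis 0.05 → 0.25, pyruvate recycling 0 → 0.2),
matching the observation that the GAPDH block and glycolytic reversal appear
between 24 and 48 hours. Control concentrations use the printed control
means where a nonzero value is printed (pyruvate and citrate 0.01, alanine
0.07 mM/mg protein; the GC-MS ion-count panel) and 1 arbitrary unit
otherwise.

What the generator does *not* emulate: raw NMR/GC-MS spectra and their
processing artefacts, batch effects, peak-overlap biases, missing values,
or between-day drift. Passing the end-to-end tests shows the analysis
pipeline is correct and well calibrated under the stated noise model — not
that the noise model captures every failure mode of real instruments.

## Numerical choices and limitations

* Distribution pruning at 1e-12 with renormalisation; simulator fixed point
  at L1 1e-12; nullspace detection at a 1e-9 relative singular-value cutoff;
  the feasible-direction search is conservative within ~1e-8.
* Problem sizes in the shipped tests and acceptance script were chosen to
  keep everything comfortably interactive: 100 generated studies for the
  effect-size recoveries, 200 for the power check, 5,000–10,000 null
  replicates for the family-wise-error calibration (binomial SE ≈ 0.002–
  0.003 at 10,000).
* The package does no flux fitting against a stoichiometric model and no EMU
  decomposition — pattern spaces here are small enough for direct
  enumeration, and pathway *fractions*, not absolute fluxes, are the target.
  Compartment-specific NAD⁺/NADH pools are discussed in the source biology
  but never computed; they are out of scope here too.
* The CLI (`inst/cli/carbontrace`) is a thin wrapper over the exported
  functions; the R API is the primary interface.
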