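---
title: "Structured mutations in finite-population evolutionary games"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structured mutations in finite-population evolutionary games}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moranmut)
```

## The model

`moranmut` studies evolutionary game dynamics in a finite, well-mixed
population of constant size $N$ evolving under the Moran process. At every
event one individual is chosen to reproduce with probability proportional to
its fitness, its offspring (possibly mutated) joins the population, and a
uniformly chosen individual — possibly the parent — is removed. Payoffs come
from a symmetric game; each individual plays every other individual but not
itself, so in a two-strategy state with $i$ copies of $A$,

$$\pi_A(i) = \frac{a(i-1) + b(N-i)}{N-1}, \qquad
  \pi_B(i) = \frac{c\,i + d(N-i-1)}{N-1}.$$

Payoff maps to fitness exponentially, $f = e^{\beta\pi}$, where $\beta \ge 0$
is the intensity of selection: $\beta = 0$ is neutral drift and
$\beta \to \infty$ is strong selection. For a single invader among $N-1$
residents the backward/forward transition ratio at state $i$ is
$e^{-\beta\,\Delta\pi(i)}$, which gives the fixation probability

$$\rho = \Bigl(1 + \sum_{k=1}^{N-1} e^{-\beta S_k}\Bigr)^{-1},
  \qquad S_k = \sum_{i=1}^{k} \Delta\pi(i).$$

### Mutation kernels

Mutation is described by a row-stochastic matrix $M$, the *mutation kernel*:
$M_{ij}$ is the probability that an offspring copied from a strategy-$i$
parent is of type $j$, with the diagonal carrying the no-mutation mass. The
classic "model-less" assumption is the uniform kernel,
$M_{ij} = \mu/(n-1)$ off the diagonal. The package treats the kernel as a
first-class modelling object: any ergodic kernel is accepted, and two
structured families are built in:

* **bitwise kernels**, where strategies are strings and mutations flip one
  position (the 3-cube of memory-one repeated-game strategies; the
  base-plus-flags space of the punishment game, where every strategy has
  exactly five single-position neighbours);
* the **loner-biased kernel** of the four-type public goods game, where
  mutations out of the abstaining state are deflated by a factor
  $\alpha \in (0,1]$ (interpretable as the rarity of mutations that
  re-enter social life, or as cultural risk aversion).

### The rare-mutation embedded chain

When mutations are rare the population is almost always monomorphic: a
mutant either fixes or dies out before the next one appears. The dynamics
then collapse to a Markov chain over monomorphic states with

$$T_{ab} \propto M_{ab}\,\rho_{ab},$$

where $\rho_{ab}$ is the fixation probability of one $b$-mutant among
$N-1$ residents of $a$. Long-run behaviour is the stationary distribution
$\pi = \pi T$. Because kernels may assign different total exit mass to
different rows (the loner kernel does), the chain uses the *absolute*
off-diagonal mutation probabilities without per-row renormalisation; the
arbitrary common row scale provably cancels from $\pi$, which is verified in
the test suite.

For two strategies the chain is reversible and
$\pi_A/\pi_B = \mu_{BA}\rho_A / (\mu_{AB}\rho_B)$. Under the exponential
mapping the fixation-ratio has the exact closed form
$\rho_A/\rho_B = \exp\!\bigl(\tfrac{\beta}{2}[(a-d)(N-2)+(b-c)N]\bigr)$, so
$A$ is more abundant in the long run iff

$$\ln\frac{\mu_{BA}}{\mu_{AB}} + \frac{\beta}{2}\bigl[(a-d)(N-2)+(b-c)N\bigr] > 0.$$

With equal mutation rates and large $N$ this is risk dominance,
$a+b > c+d$. Population size and selection intensity enter linearly but the
mutation ratio only logarithmically — so a ratio reversing any payoff
disadvantage always exists, although under strong selection in large
populations it can be astronomically large. `reversal_ratio_2x2()` therefore
reports the critical ratio together with a `log_ratio` attribute, which is
the authoritative value when the ratio itself overflows double precision.

## The two study systems

### Repeated prisoner's dilemma

The eight deterministic memory-one strategies are 3-bit codes (opening move,
reply to C, reply to D). Joint play of two automata is eventually periodic
with preperiod plus minimal cycle of at most five rounds, so the
$(1-w)$-normalised discounted payoff with continuation probability $w$ is
evaluated in closed form from the detected cycle — no truncation error. The
default one-shot payoffs are the classic $(R,S,T,P) = (3,0,5,1)$ with
$w = 0.9$ and $N = 100$.

```{r}
spec <- rpd_spec()
A <- pd_payoff_matrix(spec)
pop <- moran_population(100, 0.5)
round(stationary_distribution(embedded_chain(A, uniform_kernel(8, 1e-3,
  labels = rownames(A)), pop)), 3)
round(stationary_distribution(embedded_chain(A, bitwise_kernel(1e-3), pop)), 3)
```

Under the uniform kernel TFT carries most of the stationary mass at moderate
selection; under the bitwise kernel the mass shifts to ALLD. The statistic
`cooperative_mass()` sums the stationary mass of strategies whose *self-play*
is eventually all mutual cooperation (computed from traces, not hard-coded:
ALLC, TFT and SALLC). Across $\beta \in [0.05, 10]$ the bitwise kernel never
exceeds the uniform kernel on this statistic. Very close to neutrality
(roughly $\beta \le 0.03$ at the default parameters) both kernels approach
the uniform distribution and the ordering briefly reverses by a few percent
— a genuine feature of the model worth knowing about, which is why the
package's reduction test runs on the selection-dominated range.

### Optional public goods with punishment

Groups of $n$ are sampled without replacement from the population.
Participants (bases C and D) play a public goods game: contributors pay $c$,
the pot is multiplied by $r$ and shared among all participants; loners take
the fixed payoff $\sigma$; a group with fewer than two participants gives
the lone would-be participant $\sigma$ as well. Punishers fine targeted
group members $\mathrm{fine}$ per pair at cost $\mathrm{fine\_cost}$ per
fine; punishment applies among group members regardless of whether the game
itself is played, and nobody punishes themselves. Defaults:
$N = 100$, $n = 5$, $c = 1$, $r = 3$, $\sigma = 1$, fine $= 1$, cost
$= 0.3$.

Expected payoffs for a resident--invader pair are exact hypergeometric
expectations over group compositions (`pgg_pair_payoffs()`), verified in the
tests against exhaustive enumeration of all labelled groups at $N \le 14$.
The four-type system C, D, P, L is literally the subspace
$\{$C-NNN, D-NNN, C-NPN, L-NNN$\}$ of the 24-strategy space (base $\times$
three punishment flags), so one payoff engine serves both.

At strong selection the four-type transition structure is: D invades C and
L invades D surely; C and P drift neutrally into one another ($1/N$); L
drifts into C or P with probability $1/2$ (the first step is neutral because
a lone participant earns $\sigma$; every later step is advantageous); all
other invasions are impossible. The stationary distribution is then

$$\pi \propto (2,\; 2,\; N+2,\; 2/\alpha) \quad \text{in order } (C, D, P, L),$$

with $\alpha = 1$ for the uniform kernel — altruistic punishers dominate and
their share grows with $N$. Sociality (combined C+D+P mass exceeding the
loner mass) holds iff $\alpha (N + 6) > 2$. The package *detects* this
regime from the computed pairwise strong-selection fixation values and only
then uses the closed form; otherwise it falls back to the generic embedded
chain with a message.

```{r}
strong_selection_stationary_4(pgg_params(alpha = 0.1), "loner")
```

In the 24-strategy space at the reference selection intensity $\beta = 1$
under uniform mutations, the three leading strategies of the filtered
display are the altruistic punisher C-NPN, the cooperator-punishing loner
L-PNN and the loner-punishing defector D-NNP, jointly carrying about two
thirds of the stationary mass:

```{r}
p <- pgg_params()
ku <- uniform_kernel(24, 1e-3, labels = rand_nowak_strategies()$label)
pi24 <- pgg_stationary(p, ku, beta = 1)
head(report_distribution_24(pi24), 5)
sum(pi24[c("C-NPN", "L-PNN", "D-NNP")])
```

Self-punishing strategies (flag targeting the own base) are dropped from the
display only, never from the computation.

## Numerical choices

* **Log-space fixation sums.** All products of $e^{\beta\Delta\pi}$ terms
  are evaluated as cumulative sums with a max-shifted log-sum-exp;
  $\log\rho$ stays finite even when $\rho$ underflows, which the abundance
  margins and the reversal bisection rely on. No overflow occurs for
  $\beta\,|\pi|\,N$ up to $\sim 10^4$.
* **Strong selection is a limit, not a large number.** $\beta = \infty$ is
  routed to the exact combinatorial limit: $\rho = 0$ if any $S_k < 0$, else
  $1/(1 + \#\{k: S_k = 0\})$, with equality decided at
  $10^{-12}\max(1, |\pi|)$ because the neutral paths of the punishment game
  arise from exactly equal payoffs.
* **Stationary solver.** A deterministic null-space solve: the generator is
  rebuilt from the off-diagonal transition mass (avoiding the cancellation
  in $T_{ii}-1$ for near-identity chains), rescaled so the largest exit
  mass is $1/2$, one equation replaced by the normalisation constraint, and
  polished by one step of iterative refinement. Reducible chains and
  numerically ambiguous solves fail loudly, naming unreachable states; the
  result must satisfy $\pi T = \pi$ within $10^{-10}$.
* **Reversal bisection.** The critical mutation log-ratio is bracketed by
  doubling and bisected to $10^{-10}$; although the root has a closed form,
  locating it by bisection exercises the exact route end to end.
* **Repeated-game payoffs** are closed-form preperiod-plus-cycle sums. The
  test oracle truncates the series at 3000 rounds, deep enough that the
  geometric tail $w^{3000}\bar\pi$ sits below the $10^{-10}$ comparison
  tolerance even at $w = 0.99$.
* **Strong-selection consistency checks** compare the limit routine with
  large-$\beta$ log-space numerics at $N = 12$, the scale of the
  enumeration suites: there the smallest nonzero $|S_k|$ makes $\beta = 50$
  (four-type pairs) and $\beta = 500$ (all 552 ordered 24-strategy pairs)
  provably converged to well below $10^{-6}$. At $N = 100$ the
  hypergeometric dilution of payoff differences would require far larger
  $\beta$ for the same agreement.

## The simulator

`run_moran()` is a compiled event-level implementation used to validate the
rare-mutation analytics at finite $\mu$ and to explore the larger-$\mu$
regime. Design points:

* mutation is applied to the offspring at the moment of copying, drawn from
  the parent's kernel row, so the kernel rate and the simulator's $\mu$ are
  one and the same parameter;
* payoffs are recomputed from the current composition at every event
  (matrix games by the self-interaction-excluded average; punishment games
  by the exact hypergeometric group expectation, with punishment terms as
  exact pairwise expectations) — caching skips recomputation when an event
  copies and removes the same type, which is the common case near
  monomorphism;
* each run starts from a composition drawn uniformly at random over the
  integer simplex (not uniform over assignments); a deterministic initial
  composition is available for empirical fixation checks;
* abundance is averaged over a trailing window (default half) of each run,
  and standard errors are computed across runs, which are independent;
  within-run samples are autocorrelated and are never used for errors;
* every run uses an `mt19937_64` stream seeded by (root seed, run index),
  so results are bitwise reproducible and independent of scheduling.

A simulated population is faithful to the model, not to data: it emulates
demographic noise, mutation structure and selection exactly as specified,
but nothing about real organisms — no population structure, no
frequency-dependent or time-varying mutation, no measurement error. Passing
agreement tests therefore shows the analytics and the sampler implement the
same stochastic process, not that the process describes any particular
biological system.

The validity of the monomorphic-chain analytics requires mutations to be
much slower than fixation sweeps. As a rough documented heuristic the
package warns when $\mu N^2 > 0.1$ (a neutral sweep takes of order $N^2$
events). The warning is advisory: games with stable interior coexistence
break the approximation at much smaller $\mu$ than dominance games, as the
simulator readily demonstrates.

### Problem sizes used by the test suite

The simulation--analytics agreement checks run three systems at 50 runs
each, chosen to mix well within a few tens of seconds: the repeated PD
(bitwise kernel, $N = 40$, $\beta = 0.05$, $\mu = 5\times10^{-4}$, 40,000
generations), the four-type punishment game (loner kernel, $\alpha = 0.1$,
$N = 30$, $\beta = 0.1$, $\mu = 10^{-3}$, 100,000 generations) and the
24-strategy space (uniform kernel, $N = 30$, $\beta = 0.05$,
$\mu = 10^{-3}$, 100,000 generations). Each point is compared to the
embedded-chain stationary distribution within three standard errors. These
populations are smaller than the headline $N = 100$ systems purely so that
the embedded chain is traversed many times per run; the agreement property
itself is parameter-free.

## Known limitations

* Only non-frequency-dependent, time-constant kernels; only the Moran
  update (no pairwise-comparison/Fermi processes).
* The rare-mutation analytics are exact for the embedded chain but
  approximate the finite-$\mu$ process; the quality of the approximation
  degrades first for games with protected polymorphisms.
* Strong-selection closed forms cover the four-type punishment system in
  its standard regime; outside it (e.g. punishment too weak to deter
  invasion) the generic route is used automatically.
* The deterministic memory-one strategy set ignores stochastic reactive
  strategies, and memory is limited to the opponent's last move.
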