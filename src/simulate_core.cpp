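#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Fixed-timestep simulation of one nucleus over one nuclear cycle.
//
// Both alleles (and a background demand standing in for the other zygotic
// genes) draw initiating Pol II units from a single shared pool of size
// `capacity`.  An initiation attempt succeeds only if a free unit is
// available; the unit is held for the engagement time of its consumer
// (gene transit for a reporter allele, a fixed dwell for background and
// sequestering partial constructs) and then returns to the pool.  Fresh
// units arrive at `replenishRate` and are discarded when the pool is full;
// returning units that would overflow the pool are likewise discarded.
//
// All randomness comes from R's RNG so that set.seed() in R governs the
// simulation completely.  Frames are reported at t = 0, dt, ..., nSteps*dt
// (nSteps + 1 frames); frame 0 is the cycle onset with empty genes and OFF
// promoters.
//
// Attempts within a step (both alleles + background) are processed in a
// uniformly shuffled order so that no consumer is systematically favoured
// when the pool runs dry mid-step.
// [[Rcpp::export(name = ".sim_nucleus_cpp")]]
List sim_nucleus_cpp(int nSteps, double dt,
                     NumericVector kOn, NumericVector kOff,
                     NumericVector kLoad,
                     IntegerVector isReporter,
                     NumericVector geneLength, NumericVector loopStart,
                     NumericVector loopLength, NumericVector vEl,
                     NumericVector seqRate, IntegerVector holdSteps,
                     double unitIntensity,
                     double capacity, double replenishRate,
                     NumericVector bgRate, int bgDwellSteps,
                     bool keepTruth) {
    const int nA = kOn.size();
    const int nF = nSteps + 1;

    NumericMatrix signal(nF, nA);
    IntegerMatrix polCount(nF, nA);
    IntegerMatrix promState(nF, nA);
    NumericVector firstSuccess(nA, NA_REAL);
    IntegerVector successes(nA, 0), attempts(nA, 0);
    int bgSuccess = 0, bgAttempts = 0;

    NumericVector freePool, heldV, cumRepV, cumDiscV;
    if (keepTruth) {
        freePool = NumericVector(nF);
        heldV = NumericVector(nF);
        cumRepV = NumericVector(nF);
        cumDiscV = NumericVector(nF);
    }

    double freeU = capacity;
    long held = 0, cumRep = 0, cumDisc = 0;

    // release schedule: releases[f] = units returning at step f
    int maxHold = bgDwellSteps;
    for (int a = 0; a < nA; ++a) maxHold = std::max(maxHold, holdSteps[a]);
    std::vector<int> releases(nSteps + maxHold + 2, 0);

    std::vector<int> promOn(nA, 0);                  // promoter state
    std::vector< std::vector<int> > polInit(nA);     // init step per Pol II

    std::vector<double> pOn(nA), pOff(nA);
    for (int a = 0; a < nA; ++a) {
        pOn[a] = 1.0 - std::exp(-kOn[a] * dt);
        pOff[a] = 1.0 - std::exp(-kOff[a] * dt);
    }

    if (keepTruth) { freePool[0] = freeU; }

    std::vector<int> order;
    for (int f = 1; f <= nSteps; ++f) {
        // 1. returns due this step
        int ret = releases[f];
        held -= ret;
        for (int i = 0; i < ret; ++i) {
            if (freeU < capacity) freeU += 1.0;
            else ++cumDisc;
        }
        // 2. replenishment from the nucleoplasm
        int nRep = (int) R::rpois(replenishRate * dt);
        cumRep += nRep;
        for (int i = 0; i < nRep; ++i) {
            if (freeU < capacity) freeU += 1.0;
            else ++cumDisc;
        }
        // 3. promoter switching
        for (int a = 0; a < nA; ++a) {
            if (isReporter[a]) {
                double u = unif_rand();
                if (promOn[a]) { if (u < pOff[a]) promOn[a] = 0; }
                else           { if (u < pOn[a])  promOn[a] = 1; }
            }
        }
        // 4. gather attempts: allele a contributes id a, background id nA
        order.clear();
        for (int a = 0; a < nA; ++a) {
            int n;
            if (isReporter[a])
                n = promOn[a] ? (int) R::rpois(kLoad[a] * dt) : 0;
            else
                n = (int) R::rpois(seqRate[a] * dt);
            attempts[a] += n;
            for (int i = 0; i < n; ++i) order.push_back(a);
        }
        int nBg = (int) R::rpois(bgRate[f - 1] * dt);
        bgAttempts += nBg;
        for (int i = 0; i < nBg; ++i) order.push_back(nA);
        // Fisher-Yates shuffle with R's RNG
        for (int i = (int) order.size() - 1; i > 0; --i) {
            int j = (int) std::floor(unif_rand() * (i + 1));
            if (j > i) j = i;
            std::swap(order[i], order[j]);
        }
        // 5. process attempts against the pool
        for (size_t i = 0; i < order.size(); ++i) {
            if (freeU < 1.0) continue;
            freeU -= 1.0;
            ++held;
            int who = order[i];
            if (who == nA) {
                ++bgSuccess;
                releases[f + bgDwellSteps] += 1;
            } else {
                ++successes[who];
                releases[f + holdSteps[who]] += 1;
                if (isReporter[who]) {
                    polInit[who].push_back(f);
                    if (!R_finite(firstSuccess[who]))
                        firstSuccess[who] = f * dt;
                }
            }
        }
        // 6. record frame f
        for (int a = 0; a < nA; ++a) {
            if (!isReporter[a]) continue;
            double s = 0.0;
            int np = 0;
            std::vector<int> &pv = polInit[a];
            size_t keep = 0;
            for (size_t i = 0; i < pv.size(); ++i) {
                int age = f - pv[i];
                if (age >= holdSteps[a]) continue;  // terminated
                pv[keep++] = pv[i];
                ++np;
                double pos = vEl[a] * age * dt;
                if (pos > geneLength[a]) pos = geneLength[a];
                if (pos <= loopStart[a]) continue;
                double inLoop = pos - loopStart[a];
                if (inLoop >= loopLength[a]) s += unitIntensity;
                else s += unitIntensity * inLoop / loopLength[a];
            }
            pv.resize(keep);
            signal(f, a) = s;
            polCount(f, a) = np;
            promState(f, a) = promOn[a];
        }
        if (keepTruth) {
            freePool[f] = freeU;
            heldV[f] = (double) held;
            cumRepV[f] = (double) cumRep;
            cumDiscV[f] = (double) cumDisc;
        }
    }

    List out = List::create(
        _["signal"] = signal,
        _["polCount"] = polCount,
        _["promoterState"] = promState,
        _["firstSuccess"] = firstSuccess,
        _["successes"] = successes,
        _["attempts"] = attempts,
        _["bgSuccesses"] = bgSuccess,
        _["bgAttempts"] = bgAttempts);
    if (keepTruth) {
        out["freePool"] = freePool;
        out["held"] = heldV;
        out["cumReplenish"] = cumRepV;
        out["cumDiscard"] = cumDiscV;
    }
    return out;
}
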