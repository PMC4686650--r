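label,description
F.C.L.a.,anterior lateral fissure
F.C.L.p.,posterior lateral fissure
F.C.M.ant.,calloso-marginal fissure anterior part
F.C.M.post.,calloso-marginal fissure posterior part
F.Cal.,calcarine fissure
F.Coll.,collateral sulcus
F.I.P.,intraparietal sulcus
F.I.P.Po.C.inf.,superior postcentral intraparietal superior sulcus
F.I.P.r.int.1,primary intermediate ramus of the intraparietal sulcus
F.I.P.r.int.2,secondary intermediate ramus of the intraparietal sulcus
F.P.O.,parieto-occipital fissure
INSULA,insula
OCCIPITAL,lateral occipital complex
S.C.,central sulcus
S.C.sylvian.,central sylvian sulcus
S.Call.,callosal sulcus
S.Cu.,cuneal sulcus
S.F.inf.,inferior frontal sulcus
S.F.inf.ant.,anterior inferior frontal sulcus
S.F.int.,internal frontal sulcus
S.F.inter.,intermediate frontal sulcus
S.F.marginal.,marginal frontal sulcus
S.F.median.,median frontal sulcus
S.F.orbitaire.,orbital frontal sulcus
S.F.polaire.tr.,polar frontal sulcus
S.F.sup.,superior frontal sulcus
S.GSM.,supramarginal sulcus
S.Li.,lingual sulcus
S.O.T.lat.ant.,anterior occipito-temporal lateral sulcus
S.O.T.lat.int.,internal occipito-temporal lateral sulcus
S.O.T.lat.med.,median occipito-temporal lateral sulcus
S.O.T.lat.post.,posterior occipito-temporal lateral sulcus
S.O.p.,occipito-polar sulcus
S.Olf.,olfactory sulcus
S.Or.,orbital sulcus
S.Pa.int.,internal parietal sulcus
S.Pe.C.inf.,inferior precentral sulcus
S.Pe.C.inter.,intermediate precentral sulcus
S.Pe.C.marginal.,marginal precentral sulcus
S.Pe.C.median.,median precentral sulcus
S.Pe.C.sup.,superior precentral sulcus
S.Po.C.sup.,superior postcentral sulcus
S.Rh.,rhinal sulcus
S.T.i.ant.,anterior inferior temporal sulcus
S.T.s.,superior temporal sulcus
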