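# edflow synthetic cohort; seed=50
patient_id,arrival_iso8601,triage_level,age_group,category,t_triage_h,t_physician_h,t_observation_h,t_departure_h,disposition
p000001,2013-01-11T11:34:50,4,5,adult_nontrauma,0.000000000,0.262495944,,1.221082422,discharge
p000002,2013-01-25T20:37:33,3,4,trauma,0.000000000,0.329288820,,1.265051493,discharge
p000003,2013-01-23T11:41:21,3,2,pediatric_nontrauma,0.000000000,0.118242638,,0.787736133,discharge
p000004,2013-01-26T00:56:46,4,3,adult_nontrauma,0.000000000,0.056280571,,0.831138923,discharge
p000005,2013-01-18T16:41:59,3,3,adult_nontrauma,0.000000000,0.493666449,,1.257672251,discharge
p000006,2013-01-10T17:16:18,3,3,trauma,0.000000000,0.185235864,,3.010396367,discharge
p000007,2013-01-28T20:49:38,4,2,adult_nontrauma,0.000000000,0.060745385,,0.484519248,discharge
p000008,2013-01-06T10:01:54,4,2,pediatric_nontrauma,0.000000000,0.049591954,,0.794075621,discharge
p000009,2013-01-19T06:33:05,3,3,trauma,0.000000000,0.003593420,,0.938379918,discharge
p000010,2013-01-18T02:29:39,3,1,adult_nontrauma,0.000000000,0.017327993,,0.053333688,discharge
p000011,2013-01-01T17:09:47,3,2,trauma,0.000000000,0.266377809,,0.273673336,discharge
p000012,2013-01-11T07:38:29,3,2,adult_nontrauma,0.000000000,0.279509486,,1.104875926,discharge
p000013,2013-01-24T16:36:31,4,1,adult_nontrauma,0.000000000,0.020941622,,0.133034322,discharge
p000014,2013-01-12T09:29:26,3,2,adult_nontrauma,0.000000000,0.029301622,,0.450010318,discharge
p000015,2013-01-30T02:17:16,3,1,adult_nontrauma,0.000000000,0.036062041,,0.082014851,discharge
p000016,2013-01-19T00:17:11,4,1,adult_nontrauma,0.000000000,0.188614423,,0.518932294,discharge
p000017,2013-01-04T08:04:59,2,2,adult_nontrauma,0.000000000,0.128521543,5.481299717,111.607072064,discharge
p000018,2013-01-02T07:22:44,3,1,pediatric_nontrauma,0.000000000,0.184182350,,0.237442432,discharge
p000019,2013-01-21T12:01:29,3,1,adult_nontrauma,0.000000000,0.796734228,,1.441377937,discharge
p000020,2013-01-10T07:40:39,3,5,trauma,0.000000000,0.203582596,1.109253714,41.779507172,discharge
p000021,2013-01-28T08:28:05,4,3,pediatric_nontrauma,0.000000000,0.105841430,,0.240026933,discharge
p000022,2013-01-10T22:11:28,3,5,adult_nontrauma,0.000000000,0.054746841,0.602497172,38.232867316,admission
p000023,2013-01-05T11:50:52,4,2,adult_nontrauma,0.000000000,0.148531302,,1.276371327,discharge
p000024,2013-01-04T15:19:47,2,1,adult_nontrauma,0.000000000,0.198576100,,1.367383996,discharge
p000025,2013-01-11T07:40:48,3,5,adult_nontrauma,0.000000000,0.152603308,1.543723117,11.063180265,admission
p000026,2013-01-03T07:18:06,4,1,adult_nontrauma,0.000000000,0.122976498,,0.492562131,discharge
p000027,2013-01-03T11:08:03,3,2,adult_nontrauma,0.000000000,0.145879446,,0.484108125,discharge
p000028,2013-01-22T16:52:59,3,5,adult_nontrauma,0.000000000,0.350949957,,1.125771355,discharge
p000029,2013-01-09T10:39:22,3,2,adult_nontrauma,0.000000000,0.055815074,,0.660460936,discharge
p000030,2013-01-11T19:18:46,3,5,adult_nontrauma,0.000000000,0.102734558,,0.263615765,discharge
p000031,2013-01-22T04:19:51,3,2,adult_nontrauma,0.000000000,0.016659199,,0.582328312,discharge
p000032,2013-01-25T09:13:42,3,1,adult_nontrauma,0.000000000,0.401853775,,0.525929219,discharge
p000033,2013-01-09T01:59:43,3,3,pediatric_nontrauma,0.000000000,0.290603078,,0.952919154,discharge
p000034,2013-01-17T06:11:31,4,3,adult_nontrauma,0.000000000,0.004579039,,1.527707397,discharge
p000035,2013-01-29T14:45:55,3,2,adult_nontrauma,0.000000000,0.055852771,,0.270361301,discharge
p000036,2013-01-23T09:11:39,4,1,adult_nontrauma,0.000000000,0.055096292,,0.156277181,discharge
p000037,2013-01-26T17:30:13,3,1,adult_nontrauma,0.000000000,0.075282708,,0.335887482,discharge
p000038,2013-01-25T23:54:49,4,2,adult_nontrauma,0.000000000,0.200549660,,0.514611457,discharge
p000039,2013-01-27T06:34:13,3,2,adult_nontrauma,0.000000000,0.283499249,,1.735169447,discharge
p000040,2013-01-26T10:14:00,3,2,adult_nontrauma,0.000000000,0.124376137,,0.352106537,discharge
p000041,2013-01-05T13:29:29,3,2,adult_nontrauma,0.000000000,0.183764741,,0.797839638,discharge
p000042,2013-01-24T07:28:55,2,2,adult_nontrauma,0.000000000,0.006159090,,2.446902372,discharge
p000043,2013-01-11T23:18:35,3,4,adult_nontrauma,0.000000000,0.592487709,,0.959719835,discharge
p000044,2013-01-05T07:54:16,3,4,adult_nontrauma,0.000000000,0.078197222,,4.153366300,discharge
p000045,2013-01-01T11:02:44,3,1,adult_nontrauma,0.000000000,0.054312461,,0.915550376,discharge
p000046,2013-01-15T18:33:58,4,3,adult_nontrauma,0.000000000,0.156785776,,1.154307887,discharge
p000047,2013-01-27T01:43:49,1,1,pediatric_nontrauma,0.000000000,0.090901751,0.793963402,36.918637870,discharge
p000048,2013-01-07T12:15:39,3,4,pediatric_nontrauma,0.000000000,0.310619645,,0.415845648,discharge
p000049,2013-01-23T15:27:16,4,3,adult_nontrauma,0.000000000,0.252178897,0.538489924,30.912323240,discharge
p000050,2013-01-24T22:07:22,2,2,adult_nontrauma,0.000000000,0.119487656,,3.850075980,discharge
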