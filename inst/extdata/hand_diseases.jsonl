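{"name": "tendon sheath cyst", "desc": "Tendon sheath cyst refers to a cystic swelling containing gelatinous fluid that occurs near joints and tendon sheaths, most commonly at the back of the wrist.", "cause": "The disease is more common in the back of the wrist and foot; repetitive strain of the joint capsule and tendon sheath is the usual cause.", "prevention": "Tendon sheath cysts pay attention to rest in the affected area and avoid repetitive wrist strain.", "cure_lasttime": "1–3 weeks", "cure_way": ["surgical therapy", "rehabilitation therapy", "supportive therapy"], "cured_probe": "80%", "easy_get": "more common in young and middle-aged people", "symptoms": ["round cystic mass at the wrist", "local soreness on exertion"], "departments": ["orthopedics"], "recommended_foods": ["tofu and seafood soup", "stewed lamb with persimmons"], "avoided_foods": ["fried dough sticks"], "complications": []}
{"name": "tenosynovitis", "desc": "Tenosynovitis is inflammation of the synovial sheath that surrounds a tendon, typically from overuse of the hand and wrist.", "cause": "Chronic repetitive friction between tendon and sheath, cold exposure, or infection.", "prevention": "Warm up before repetitive hand work and take regular breaks.", "cure_lasttime": "2–4 weeks", "cure_way": ["drug therapy", "physiotherapy", "surgical release"], "cured_probe": "95%", "easy_get": "people who perform repetitive manual work", "symptoms": ["pain along the tendon", "swelling and tenderness", "restricted finger movement"], "departments": ["hand surgery"], "recommended_foods": ["walnut", "spinach"], "avoided_foods": ["chili peppers"], "recommended_drugs": ["ibuprofen sustained-release capsules"], "drug_producers": [["Sino Pharma", "ibuprofen sustained-release capsules"]], "complications": ["purulent dactylitis"]}
{"name": "Renault's disease", "desc": "Renault's disease is an episodic vasospastic disorder of the fingers triggered by cold or emotion, with characteristic colour changes of the skin.", "cause": "Vasospasm of the digital arteries; often associated with autoimmune conditions.", "prevention": "Keep the hands warm and avoid smoking.", "easy_get": "more common in young women", "symptoms": ["finger pallor then cyanosis on cold exposure", "numbness and tingling"], "departments": ["rheumatic immune disease"], "recommended_foods": ["ginger tea"], "avoided_foods": ["iced drinks"], "complications": []}
{"name": "hand flexor tendon injury", "desc": "Injury of the flexor tendons of the hand, usually from sharp lacerations, leaving the patient unable to bend one or more fingers.", "cause": "Cuts on the palmar side of the hand or forceful hyperextension.", "prevention": "Use protective gloves when handling sharp tools.", "cure_lasttime": "6–8 weeks", "cure_way": ["surgical repair", "splinting", "rehabilitation therapy"], "cured_probe": "85%", "easy_get": "manual workers handling sharp objects", "symptoms": ["inability to flex the finger", "pain at the injury site"], "departments": ["hand surgery"], "recommended_foods": ["cashew"], "avoided_foods": ["strong liquor"], "complications": ["joint stiffness"]}
{"name": "Achilles tendinitis", "desc": "Achilles tendinitis is overuse inflammation of the Achilles tendon; it is included here as a comparative tendon disorder.", "cause": "Sudden increases in running load or tight calf muscles.", "prevention": "Stretch the calf and increase training load gradually.", "cure_lasttime": "4–6 weeks", "cure_way": ["rest", "physiotherapy"], "cured_probe": "90%", "easy_get": "runners and jumpers", "symptoms": ["heel cord pain", "morning stiffness of the ankle"], "departments": ["sports medicine"], "recommended_foods": ["salmon"], "avoided_foods": ["chicken wings"], "complications": []}
{"name": "thallium poisoning", "desc": "Thallium poisoning is a heavy-metal intoxication that produces painful peripheral neuropathy of the hands and feet and hair loss.", "cause": "Ingestion of thallium salts from contaminated food or occupational exposure.", "prevention": "Strict control of thallium-containing compounds.", "cure_lasttime": "4–8 weeks", "cure_way": ["chelation therapy", "supportive therapy"], "cured_probe": "70%", "easy_get": "workers in thallium-processing industries", "symptoms": ["burning pain in the hands and feet", "hair loss"], "departments": ["emergency medicine"], "recommended_drugs": ["Ganlu Renqing Mangjue"], "drug_producers": [["Renqing Mangjue", "Ganlu Renqing Mangjue"]], "complications": []}
{"name": "distal radius fracture", "desc": "A break of the radius close to the wrist, the most common fracture of the upper limb, typically after a fall on an outstretched hand.", "cause": "Fall on the outstretched hand; osteoporosis increases risk.", "prevention": "Fall prevention and bone-density management in older adults.", "cure_lasttime": "6–12 weeks", "cure_way": ["closed reduction and casting", "surgical fixation", "rehabilitation therapy"], "cured_probe": "92%", "easy_get": "older adults with osteoporosis and children", "symptoms": ["wrist deformity", "swelling and pain", "restricted wrist movement"], "departments": ["orthopedics"], "recommended_recipes": ["fried eggplant with egg"], "recommended_foods": ["milk"], "avoided_foods": ["carbonated drinks"], "complications": ["joint stiffness"]}
{"name": "trigger finger", "desc": "Trigger finger is stenosing tenosynovitis of a digital flexor tendon: the finger catches or locks when bent and snaps straight.", "cause": "Thickening of the A1 pulley narrowing the tendon sheath.", "prevention": "Avoid prolonged forceful gripping.", "cure_lasttime": "2–6 weeks", "cure_way": ["splinting", "steroid injection", "surgical release"], "cured_probe": "90%", "easy_get": "middle-aged women and people with diabetes", "symptoms": ["painful clicking when bending the finger", "finger locked in flexion"], "departments": ["hand surgery"], "recommended_foods": ["pumpkin porridge"], "avoided_foods": ["barbecue"], "complications": []}
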